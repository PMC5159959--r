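series	metric	year	value
count	deaths	1990	37465
count	deaths	2013	60402
count	dalys	1990	953087
count	dalys	2013	1353407
count	ylls	1990	915402
count	ylls	2013	1291703
count	ylds	1990	37685
count	ylds	2013	61704
rate	deaths	1990	78
rate	deaths	2013	64
rate	dalys	1990	1989
rate	dalys	2013	1439
rate	ylls	1990	1910
rate	ylls	2013	1373
rate	ylds	1990	79
rate	ylds	2013	66
proportion_all	deaths	1990	4.2
proportion_all	deaths	2013	8.1
proportion_all	dalys	1990	1.6
proportion_all	dalys	2013	3.0
rate_fruit_dalys	dalys	1990	2113
rate_fruit_dalys	dalys	2013	1632
count_cvd_total	deaths	2013	121211
count_cvd_diet	deaths	2013	53375
count_diet_total	deaths	2013	60402
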