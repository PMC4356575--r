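country,t1,t2,t3,t4,t5,t6,t7
Algeria,12.21,19.59,19.35,10.14,25.58,9.91,3.23
Brazil,15.91,20.64,21.59,10.98,17.61,7.77,5.49
China-1,15.34,21.02,23.86,10.23,16.48,10.51,2.56
China-2,15.80,21.97,20.24,9.74,18.40,11.36,2.49
Croatia,14.61,18.26,19.94,12.64,17.98,9.27,7.30
Czech Republic,14.41,18.29,21.47,8.95,23.86,4.67,8.35
France,12.17,18.14,22.43,12.17,19.81,8.35,6.92
Germany,11.21,17.29,19.16,19.16,16.82,7.48,8.88
Greece-1,14.24,17.80,23.15,11.57,17.80,7.72,7.72
Greece-2,13.49,17.21,17.67,17.21,14.42,13.02,6.98
Italy,11.11,17.59,13.89,12.96,25.00,11.11,8.33
Japan,13.63,19.86,22.17,11.32,17.09,10.39,5.54
Lithuania,14.84,20.55,18.95,11.87,20.09,9.13,4.57
Mexico,15.36,18.43,24.23,6.83,22.87,8.87,3.41
New Zealand,10.64,13.68,18.84,15.50,22.80,10.33,8.21
Poland,12.00,15.50,21.50,15.00,18.00,12.00,6.00
Portugal,16.42,20.23,17.60,9.38,21.99,7.04,7.33
Republic of Serbia,14.96,22.44,19.70,12.22,16.71,7.23,6.73
Russia,12.77,19.39,22.38,12.21,17.81,10.09,5.36
Spain,12.19,19.66,22.80,11.40,19.27,9.83,4.85
Sweden,15.08,19.08,21.54,9.85,20.62,8.00,5.85
Turkey,13.05,16.63,23.37,11.58,17.68,9.68,8.00
UK,10.06,15.08,23.46,17.32,18.44,6.70,8.94
USA,14.06,15.48,22.24,11.21,17.97,12.10,6.94
Total sample,13.81,18.94,21.30,11.48,19.38,9.17,5.92
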