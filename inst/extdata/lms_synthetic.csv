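measure,sex,age_years,L,M,S
height,F,1,1,76.94,0.04
height,F,1.5,1,80.54,0.04
height,F,2,1,84.06,0.04
height,F,2.5,1,87.5,0.04
height,F,3,1,90.86,0.04
height,F,3.5,1,94.14,0.04
height,F,4,1,97.34,0.04
height,F,4.5,1,100.46,0.04
height,F,5,1,103.5,0.04
height,F,5.5,1,106.46,0.04
height,F,6,1,109.34,0.04
height,F,6.5,1,112.14,0.04
height,F,7,1,114.86,0.04
height,F,7.5,1,117.5,0.04
height,F,8,1,120.06,0.04
height,M,1,1,78.04,0.04
height,M,1.5,1,81.69,0.04
height,M,2,1,85.26,0.04
height,M,2.5,1,88.75,0.04
height,M,3,1,92.16,0.04
height,M,3.5,1,95.49,0.04
height,M,4,1,98.74,0.04
height,M,4.5,1,101.91,0.04
height,M,5,1,105,0.04
height,M,5.5,1,108.01,0.04
height,M,6,1,110.94,0.04
height,M,6.5,1,113.79,0.04
height,M,7,1,116.56,0.04
height,M,7.5,1,119.25,0.04
height,M,8,1,121.86,0.04
bmi,F,1,-1.58,16.345,0.08
bmi,F,1.5,-1.57,16.236,0.08
bmi,F,2,-1.56,16.14,0.08
bmi,F,2.5,-1.55,16.056,0.08
bmi,F,3,-1.54,15.985,0.08
bmi,F,3.5,-1.53,15.926,0.08
bmi,F,4,-1.52,15.88,0.08
bmi,F,4.5,-1.51,15.846,0.08
bmi,F,5,-1.5,15.825,0.08
bmi,F,5.5,-1.49,15.816,0.08
bmi,F,6,-1.48,15.82,0.08
bmi,F,6.5,-1.47,15.836,0.08
bmi,F,7,-1.46,15.865,0.08
bmi,F,7.5,-1.45,15.906,0.08
bmi,F,8,-1.44,15.96,0.08
bmi,M,1,-1.78,16.545,0.078
bmi,M,1.5,-1.77,16.436,0.078
bmi,M,2,-1.76,16.34,0.078
bmi,M,2.5,-1.75,16.256,0.078
bmi,M,3,-1.74,16.185,0.078
bmi,M,3.5,-1.73,16.126,0.078
bmi,M,4,-1.72,16.08,0.078
bmi,M,4.5,-1.71,16.046,0.078
bmi,M,5,-1.7,16.025,0.078
bmi,M,5.5,-1.69,16.016,0.078
bmi,M,6,-1.68,16.02,0.078
bmi,M,6.5,-1.67,16.036,0.078
bmi,M,7,-1.66,16.065,0.078
bmi,M,7.5,-1.65,16.106,0.078
bmi,M,8,-1.64,16.16,0.078
muac,F,1,0.4,14.37,0.068
muac,F,1.5,0.4,14.505,0.068
muac,F,2,0.4,14.64,0.068
muac,F,2.5,0.4,14.775,0.068
muac,F,3,0.4,14.91,0.068
muac,F,3.5,0.4,15.045,0.068
muac,F,4,0.4,15.18,0.068
muac,F,4.5,0.4,15.315,0.068
muac,F,5,0.4,15.45,0.068
muac,F,5.5,0.4,15.585,0.068
muac,F,6,0.4,15.72,0.068
muac,F,6.5,0.4,15.855,0.068
muac,F,7,0.4,15.99,0.068
muac,F,7.5,0.4,16.125,0.068
muac,F,8,0.4,16.26,0.068
muac,M,1,0.4,14.57,0.066
muac,M,1.5,0.4,14.705,0.066
muac,M,2,0.4,14.84,0.066
muac,M,2.5,0.4,14.975,0.066
muac,M,3,0.4,15.11,0.066
muac,M,3.5,0.4,15.245,0.066
muac,M,4,0.4,15.38,0.066
muac,M,4.5,0.4,15.515,0.066
muac,M,5,0.4,15.65,0.066
muac,M,5.5,0.4,15.785,0.066
muac,M,6,0.4,15.92,0.066
muac,M,6.5,0.4,16.055,0.066
muac,M,7,0.4,16.19,0.066
muac,M,7.5,0.4,16.325,0.066
muac,M,8,0.4,16.46,0.066
muac_ext,F,1,0.4,14.37,0.07
muac_ext,F,1.5,0.4,14.505,0.07
muac_ext,F,2,0.4,14.64,0.07
muac_ext,F,2.5,0.4,14.775,0.07
muac_ext,F,3,0.4,14.91,0.07
muac_ext,F,3.5,0.4,15.045,0.07
muac_ext,F,4,0.4,15.18,0.07
muac_ext,F,4.5,0.4,15.315,0.07
muac_ext,F,5,0.4,15.45,0.07
muac_ext,F,5.5,0.4,15.585,0.07
muac_ext,F,6,0.4,15.72,0.07
muac_ext,F,6.5,0.4,15.855,0.07
muac_ext,F,7,0.4,15.99,0.07
muac_ext,F,7.5,0.4,16.125,0.07
muac_ext,F,8,0.4,16.26,0.07
muac_ext,M,1,0.4,14.57,0.068
muac_ext,M,1.5,0.4,14.705,0.068
muac_ext,M,2,0.4,14.84,0.068
muac_ext,M,2.5,0.4,14.975,0.068
muac_ext,M,3,0.4,15.11,0.068
muac_ext,M,3.5,0.4,15.245,0.068
muac_ext,M,4,0.4,15.38,0.068
muac_ext,M,4.5,0.4,15.515,0.068
muac_ext,M,5,0.4,15.65,0.068
muac_ext,M,5.5,0.4,15.785,0.068
muac_ext,M,6,0.4,15.92,0.068
muac_ext,M,6.5,0.4,16.055,0.068
muac_ext,M,7,0.4,16.19,0.068
muac_ext,M,7.5,0.4,16.325,0.068
muac_ext,M,8,0.4,16.46,0.068
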