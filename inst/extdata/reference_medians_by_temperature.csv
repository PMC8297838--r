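property,day,temperature,control,light,medium,heavy
movementLength,1,low,0.104,0.082,0.084,0.086
movementLength,1,intermediate,0.069,0.076,0.063,0.063
movementLength,1,high,0.059,0.057,0.054,0.059
movementLength,2,low,0.092,0.079,0.075,0.077
movementLength,2,intermediate,0.075,0.071,0.078,0.074
movementLength,2,high,0.066,0.063,0.061,0.071
movementLength,3,low,0.105,0.072,0.076,0.070
movementLength,3,intermediate,0.076,0.085,0.084,0.075
movementLength,3,high,0.065,0.069,0.068,0.062
movementLengthMax,1,low,0.515,0.443,0.327,0.341
movementLengthMax,1,intermediate,0.345,0.304,0.283,0.247
movementLengthMax,1,high,0.241,0.311,0.230,0.224
movementLengthMax,2,low,0.451,0.311,0.257,0.283
movementLengthMax,2,intermediate,0.326,0.372,0.309,0.319
movementLengthMax,2,high,0.295,0.267,0.276,0.282
movementLengthMax,3,low,0.528,0.396,0.291,0.334
movementLengthMax,3,intermediate,0.365,0.449,0.354,0.303
movementLengthMax,3,high,0.291,0.295,0.310,0.282
movementSum,1,low,22.05,17.07,13.47,10.69
movementSum,1,intermediate,16.32,12.32,14.43,9.19
movementSum,1,high,7.97,10.36,7.39,6.93
movementSum,2,low,22.56,16.08,11.33,11.28
movementSum,2,intermediate,19.70,18.17,15.90,14.91
movementSum,2,high,17.56,15.39,16.64,11.60
movementSum,3,low,21.87,16.35,12.15,11.73
movementSum,3,intermediate,18.04,22.91,17.84,12.98
movementSum,3,high,11.40,16.47,10.73,10.05
movementSpeed,1,low,0.067,0.056,0.048,0.051
movementSpeed,1,intermediate,0.066,0.061,0.064,0.055
movementSpeed,1,high,0.061,0.054,0.056,0.047
movementSpeed,2,low,0.063,0.050,0.048,0.042
movementSpeed,2,intermediate,0.067,0.064,0.060,0.053
movementSpeed,2,high,0.066,0.063,0.061,0.053
movementSpeed,3,low,0.065,0.048,0.044,0.040
movementSpeed,3,intermediate,0.069,0.073,0.065,0.055
movementSpeed,3,high,0.069,0.070,0.066,0.053
restingDuration,1,low,1.45,1.53,2.34,2.92
restingDuration,1,intermediate,2.02,1.97,2.57,2.28
restingDuration,1,high,4.38,2.62,3.54,4.08
restingDuration,2,low,1.25,1.50,2.18,2.60
restingDuration,2,intermediate,1.49,1.75,1.81,1.66
restingDuration,2,high,1.65,1.72,1.71,2.65
restingDuration,3,low,1.49,1.31,2.11,2.66
restingDuration,3,intermediate,1.96,1.55,1.95,1.96
restingDuration,3,high,2.92,2.07,2.59,2.36
restingFrequency,1,low,105,127,119,105
restingFrequency,1,intermediate,107,116,103,117
restingFrequency,1,high,80,102,97,92
restingFrequency,2,low,105,113,116,98
restingFrequency,2,intermediate,115,109,107,119
restingFrequency,2,high,99,103,100,105
restingFrequency,3,low,111,121,114,101
restingFrequency,3,intermediate,106,106,116,109
restingFrequency,3,high,98,114,104,111
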