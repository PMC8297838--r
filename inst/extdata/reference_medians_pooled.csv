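property,day,control,light,medium,heavy
movementLength,1,0.075,0.070,0.071,0.065
movementLength,2,0.078,0.070,0.073,0.072
movementLength,3,0.080,0.077,0.076,0.068
movementLengthMax,1,0.386,0.305,0.289,0.273
movementLengthMax,2,0.384,0.311,0.276,0.287
movementLengthMax,3,0.406,0.385,0.317,0.297
movementSum,1,15.63,12.21,11.79,9.19
movementSum,2,19.84,16.08,15.66,12.04
movementSum,3,18.97,17.63,13.34,11.73
movementSpeed,1,0.064,0.057,0.056,0.051
movementSpeed,2,0.066,0.061,0.055,0.050
movementSpeed,3,0.069,0.065,0.059,0.050
restingDuration,1,2.03,2.14,2.76,2.87
restingDuration,2,1.40,1.66,1.94,2.59
restingDuration,3,1.86,1.72,2.23,2.31
restingFrequency,1,101,118,105,109
restingFrequency,2,111,109,107,109
restingFrequency,3,106,111,109,111
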