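term,estimate,std_error,df,t_value,p_value
(Intercept),0.8481,2.4375,294.7989,0.3479,0.7281
high temperature,-10.4746,3.5562,349.7777,-2.9455,0.0034
low temperature,10.8655,3.2454,258.9370,3.3480,0.0009
tag weight,-0.0077,0.0012,167.3106,-6.3737,0.0000
animal weight,0.0217,0.0031,303.1101,7.1041,0.0000
high temperature:tag weight,0.0052,0.0017,168.0552,3.0456,0.0027
low temperature:tag weight,-0.0063,0.0017,166.9246,-3.6653,0.0003
high temperature:animal weight,0.0077,0.0044,360.8046,1.7496,0.0810
low temperature:animal weight,-0.0109,0.0039,268.4809,-2.7685,0.0060
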