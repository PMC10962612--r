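sample_id	individual_id	day	group
ctrl01_d0030	ctrl01	30	control
ctrl01_d0060	ctrl01	60	control
ctrl01_d0090	ctrl01	90	control
ctrl01_d0120	ctrl01	120	control
ctrl01_d0150	ctrl01	150	control
ctrl01_d0180	ctrl01	180	control
ctrl02_d0030	ctrl02	30	control
ctrl02_d0060	ctrl02	60	control
ctrl02_d0090	ctrl02	90	control
ctrl02_d0120	ctrl02	120	control
ctrl02_d0150	ctrl02	150	control
ctrl02_d0180	ctrl02	180	control
sero01_d0030	sero01	30	seroconverter
sero01_d0060	sero01	60	seroconverter
sero01_d0090	sero01	90	seroconverter
sero01_d0120	sero01	120	seroconverter
sero01_d0150	sero01	150	seroconverter
sero01_d0180	sero01	180	seroconverter
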