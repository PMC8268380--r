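mediator,dpdx_exposure,dpdx_mortality,beta_los,beta_chg
infection,0.0190,0.0176,8.42,62169
shock,0.0025,0.0521,8.68,85247
bleeding,0.0050,0.0121,3.15,30770
wound_disruption,0.0060,0.0132,11.09,86760
digestive,0.0135,0.0046,3.94,23378
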