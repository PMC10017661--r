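wavelength,epsHbO2,epsHb
665,320.0,3227.2
860,1069.6,692.36
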