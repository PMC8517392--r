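# seed: 733339
# note: synthetic fixture
subject_id,t_mvc_s,t_avo_s,t_avc_s,t_mvo_s
NC0001,0,0.061039,0.358955,0.441139
NC0002,0,0.057153,0.372559,0.47251
T2DM0001,0,0.051397,0.299942,0.380079
T2DM0002,0,0.0693,0.376141,0.454945
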