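sensor_id,blue,green,red,nir,swir1,swir2,source
TM,0.0315,0.2021,0.3102,0.1594,-0.6806,-0.6109,Crist 1985 reflectance-based
ETM+,0.0315,0.2021,0.3102,0.1594,-0.6806,-0.6109,Crist 1985 reflectance-based
OLI,0.1511,0.1973,0.3283,0.3407,-0.7117,-0.4559,Baig et al. 2014
SYNTHETIC,0.0315,0.2021,0.3102,0.1594,-0.6806,-0.6109,TM set reused
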