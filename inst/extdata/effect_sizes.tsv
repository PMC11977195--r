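network	metric	beta_age	beta_sex	r2_target	baseline_mean	baseline_sd
default_mode	CTh	-0.59	0	0.3481	2.8	0.15
dorsal_attention	CTh	-0.40	0	0.16	2.8	0.15
somatomotor	CTh	-0.40	0	0.16	2.8	0.15
visual	CTh	-0.61	0	0.3721	2.8	0.15
default_mode	GMvol	-0.37	0	0.1369	120000	12000
dorsal_attention	GMvol	-0.34	0	0.1156	120000	12000
visual	GMvol	-0.29	0	0.0841	120000	12000
limbic	MD	-0.42	0	0.1764	0.80	0.04
somatomotor	MD	0.34	0	0.1156	0.80	0.04
visual	f_neurite	0.728011	0	0.53	0.40	0.04
somatomotor	f_neurite	0.728011	0	0.53	0.40	0.04
dorsal_attention	f_neurite	0.728011	0	0.53	0.40	0.04
ventral_attention	f_neurite	0.728011	0	0.53	0.40	0.04
limbic	f_neurite	0.728011	0	0.53	0.40	0.04
frontoparietal	f_neurite	0.728011	0	0.53	0.40	0.04
default_mode	f_neurite	0.728011	0	0.53	0.40	0.04
visual	v_ic	0.678233	0	0.46	0.45	0.05
somatomotor	v_ic	0.678233	0	0.46	0.45	0.05
dorsal_attention	v_ic	0.678233	0	0.46	0.45	0.05
ventral_attention	v_ic	0.678233	0	0.46	0.45	0.05
limbic	v_ic	0.678233	0	0.46	0.45	0.05
frontoparietal	v_ic	0.678233	0	0.46	0.45	0.05
default_mode	v_ic	0.678233	0	0.46	0.45	0.05
visual	ODI	0.648074	0	0.42	0.45	0.04
somatomotor	ODI	0.648074	0	0.42	0.45	0.04
dorsal_attention	ODI	0.648074	0	0.42	0.45	0.04
ventral_attention	ODI	0.648074	0	0.42	0.45	0.04
limbic	ODI	0.648074	0	0.42	0.45	0.04
frontoparietal	ODI	0.648074	0	0.42	0.45	0.04
default_mode	ODI	0.648074	0	0.42	0.45	0.04
visual	R_soma	-0.692820	0	0.48	11.0	0.6
somatomotor	R_soma	-0.692820	0	0.48	11.0	0.6
dorsal_attention	R_soma	-0.692820	0	0.48	11.0	0.6
ventral_attention	R_soma	-0.692820	0	0.48	11.0	0.6
limbic	R_soma	-0.692820	0	0.48	11.0	0.6
frontoparietal	R_soma	-0.692820	0	0.48	11.0	0.6
default_mode	R_soma	-0.692820	0	0.48	11.0	0.6
dorsal_attention	f_soma	-0.346410	0	0.12	0.30	0.03
limbic	f_soma	-0.30	0	0.09	0.30	0.03
somatomotor	f_soma	-0.479583	0	0.23	0.30	0.03
default_mode	f_extracellular	-0.346410	0	0.12	0.30	0.03
limbic	f_extracellular	-0.458258	0	0.21	0.30	0.03
visual	f_extracellular	-0.30	0	0.09	0.30	0.03
visual	FA	-0.519615	0	0.27	0.15	0.02
somatomotor	FA	-0.519615	0	0.27	0.15	0.02
dorsal_attention	FA	-0.519615	0	0.27	0.15	0.02
ventral_attention	FA	-0.519615	0	0.27	0.15	0.02
frontoparietal	FA	-0.519615	0	0.27	0.15	0.02
default_mode	FA	-0.519615	0	0.27	0.15	0.02
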