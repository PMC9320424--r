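group	eqtl_tissue	tftarget_tissue	biosample
cortex	Brain_Cortex	brain cortex	Brain Dorsolateral Prefrontal Cortex
cerebellum	Brain_Cerebellar_Hemisphere	cerebellum	Brain Cingulate Gyrus
hippocampus	Brain_Hippocampus	hippocampus	Brain Hippocampus Middle
basal_ganglia	Brain_Putamen_basal_ganglia	putamen	Brain Anterior Caudate
astrocyte	Brain_Cortex	astrocyte	Astrocytes
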