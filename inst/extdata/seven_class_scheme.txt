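# Default seven-class subcellular location scheme.
# The synonym map is a best-effort stand-in for the label->class mappings used
# by the major databases and predictors; extend or replace it for your data.
classes: secreted, nucleus, cytoplasm, plasma membrane, mitochondrion, endoplasmic reticulum, Golgi apparatus

# secreted
extracellular	secreted
extracellular space	secreted
extracellular region	secreted
extracellular matrix	secreted

# nucleus
nuclear	nucleus
nucleoplasm	nucleus
nucleolus	nucleus
nuclear membrane	nucleus
nuclear bodies	nucleus
nuclear speckles	nucleus
chromosome	nucleus

# cytoplasm
cytosol	cytoplasm
cytoplasmic	cytoplasm
cytoplasmic bodies	cytoplasm

# plasma membrane
cell membrane	plasma membrane
cell surface	plasma membrane
plasmalemma	plasma membrane

# mitochondrion
mitochondria	mitochondrion
mitochondrial	mitochondrion
mitochondrial membrane	mitochondrion
mitochondrial matrix	mitochondrion

# endoplasmic reticulum
er	endoplasmic reticulum
er membrane	endoplasmic reticulum
endoplasmic reticulum membrane	endoplasmic reticulum
sarcoplasmic reticulum	endoplasmic reticulum

# Golgi apparatus
golgi	Golgi apparatus
golgi membrane	Golgi apparatus
golgi apparatus membrane	Golgi apparatus

# compartments outside the seven-class projection
vesicles	unmappable
endosome	unmappable
lysosome	unmappable
peroxisome	unmappable
vacuole	unmappable
cytoskeleton	unmappable
centrosome	unmappable
cell junctions	unmappable
chloroplast	unmappable
plastid	unmappable
membrane	unmappable
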