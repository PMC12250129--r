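# Reference adult male phantom organ masses (editable external standard
# constants for a 70 kg adult; not study data). TOTAL_BODY mass_g is in kg.
organ,mass_g
heart_contents,500
heart,316
liver,1910
spleen,183
lung,1000
kidney,299
muscle,28000
brain,1420
bone,10500
small_intestine,677
red_marrow,1120
testes,39.1
thyroid,20.7
skin,3010
TOTAL_BODY,70
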