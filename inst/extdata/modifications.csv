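name,plus,minus,requires_base,scope
guanine_depurination,H2O,C5H5N5O,G,table3
guanine_shortmer,,C11H14N5O7P,G,table3
methylation,CH2,,,table3
fluoride,F,OH,,table3
galnac,C87H140O41N,,,table3
o_to_s,S,O,,table3
shortmer_A,,C10H12N5O5P,A,impurity
shortmer_C,,C9H12N3O6P,C,impurity
adenine_depurination,H2O,C5H5N5,A,impurity
na_adduct,Na,H,,impurity
k_adduct,K,H,,impurity
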