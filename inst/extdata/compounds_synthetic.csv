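compound_id,name,formula,monoisotopic_mass
cpd_glucose,D-glucose,C6H12O6,
cpd_fructose,D-fructose,C6H12O6,
cpd_leucine,L-leucine,C6H13NO2,
cpd_isoleucine,L-isoleucine,C6H13NO2,
cpd_valine,L-valine,C5H11NO2,
cpd_betaine,glycine betaine,C5H11NO2,
cpd_glycine,glycine,C2H5NO2,
cpd_taurine,taurine,C2H7NO3S,
cpd_alanine,L-alanine,C3H7NO2,
cpd_serine,L-serine,C3H7NO3,
cpd_threonine,L-threonine,C4H9NO3,
cpd_methionine,L-methionine,C5H11NO2S,
cpd_phenylalanine,L-phenylalanine,C9H11NO2,
cpd_tyrosine,L-tyrosine,C9H11NO3,
cpd_tryptophan,L-tryptophan,C11H12N2O2,
cpd_lysine,L-lysine,C6H14N2O2,
cpd_histidine,L-histidine,C6H9N3O2,
cpd_cholic_acid,cholic acid,C24H40O5,
cpd_cdca,chenodeoxycholic acid,C24H40O4,
cpd_dca,deoxycholic acid,C24H40O4,
cpd_gca,glycocholic acid,C26H43NO6,
cpd_tca,taurocholic acid,C26H45NO6S,
cpd_palmitic,palmitic acid,C16H32O2,
cpd_oleic,oleic acid,C18H34O2,
cpd_linoleic,linoleic acid,C18H32O2,
cpd_ala_fa,alpha-linolenic acid,C18H30O2,
cpd_dha,docosahexaenoic acid,C22H32O2,
cpd_octanoic,octanoic acid,C8H16O2,
cpd_decanoic,decanoic acid,C10H20O2,
cpd_lauric,lauric acid,C12H24O2,
cpd_creatinine,creatinine,C4H7N3O,
cpd_uric_acid,uric acid,C5H4N4O3,
cpd_citrate,citric acid,C6H8O7,
cpd_lactate,lactic acid,C3H6O3,
cpd_pyruvate,pyruvic acid,C3H4O3,
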