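source_id,n_species_assigned
besnard_etal,1
bohley_etal,1
bruhl_wilson,8
caddy_retalic,154
carolin_etal,2
clayton_etal,3
dandrea_etal,1
ehleringer_monson,3
feodorova_etal,1
guillaume_etal,9
hancock_etal,7
herppich_herppich,1
holtum_etal_a,2
holtum_etal_b,1
horn_etal,10
kadereit_etal,1
kattge_etal,1013
koch_kennedy,1
madhusudana_rao_etal,1
metcalfe,3
osborne_etal,6
pate_etal,8
sage,657
sage_etal,27
sayed,2
schmidt_stewart,1
taylor_etal,1
thiede_eggli,2
ting,1
watson_dallwitz_a,637
watson_dallwitz_b,2
winter,1
winter_etal_a,2
winter_etal_b,3
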