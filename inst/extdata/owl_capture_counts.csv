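species,within_model,within_buffer,outside_buffer,total
flammulated_owl,248,30,13,291
western_screech_owl,34,39,60,137
whiskered_screech_owl,71,41,0,112
great_horned_owl,125,13,10,148
northern_pygmy_owl,47,21,1,69
long_eared_owl,14,4,5,23
boreal_owl,17,3,0,20
northern_saw_whet_owl,22,6,6,34
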