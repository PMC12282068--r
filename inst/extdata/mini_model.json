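{"format":"morp-model","version":1,"type":"stoichiometric_model","metabolites":[{"id":"a_e","name":"a_e","formula":"C6","compartment":"e","is_boundary":false},{"id":"b_e","name":"b_e","formula":"C3","compartment":"e","is_boundary":false},{"id":"c_e","name":"c_e","formula":"C3","compartment":"e","is_boundary":false},{"id":"a","name":"a","formula":"C6","compartment":"c","is_boundary":false},{"id":"m1","name":"m1","formula":"C6","compartment":"c","is_boundary":false},{"id":"m2","name":"m2","formula":"C3","compartment":"c","is_boundary":false},{"id":"b","name":"b","formula":"C3","compartment":"c","is_boundary":false},{"id":"c","name":"c","formula":"C3","compartment":"c","is_boundary":false}],"reactions":[{"id":"EX_a","lb":-5,"ub":0,"kind":"exchange","stoichiometry":{"a_e":-1}},{"id":"EX_b","lb":0,"ub":1000,"kind":"exchange","stoichiometry":{"b_e":-1}},{"id":"EX_c","lb":0,"ub":1000,"kind":"exchange","stoichiometry":{"c_e":-1}},{"id":"Ta","lb":0,"ub":1000,"kind":"metabolic","stoichiometry":{"a_e":-1,"a":1}},{"id":"ISO","lb":-1000,"ub":1000,"kind":"metabolic","stoichiometry":{"a":-1,"m1":1}},{"id":"SPLIT","lb":0,"ub":1000,"kind":"metabolic","stoichiometry":{"m1":-1,"m2":2}},{"id":"RB1","lb":0,"ub":1000,"kind":"metabolic","stoichiometry":{"m2":-1,"b":1}},{"id":"RB2","lb":0,"ub":1000,"kind":"metabolic","stoichiometry":{"b":-1,"b_e":1}},{"id":"RC1","lb":0,"ub":1000,"kind":"metabolic","stoichiometry":{"m2":-1,"c":1}},{"id":"RC2","lb":0,"ub":1000,"kind":"metabolic","stoichiometry":{"c":-1,"c_e":1}},{"id":"DRAIN","lb":0,"ub":0.5,"kind":"metabolic","stoichiometry":{"m2":-1}},{"id":"bio","lb":0,"ub":1000,"kind":"biomass","stoichiometry":{"m1":-0.5}}],"biomass_id":"bio","objective_default":"bio"}
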