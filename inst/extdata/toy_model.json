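{
  "id": "toy4",
  "metabolites": [
    {"id": "A_c", "name": "metabolite A", "compartment": "c"},
    {"id": "B_c", "name": "metabolite B", "compartment": "c"},
    {"id": "C_c", "name": "metabolite C", "compartment": "c"}
  ],
  "reactions": [
    {"id": "EX_A", "name": "A exchange", "stoichiometry": {"A_c": -1},
     "lb": -10, "ub": 1000, "reversible": true, "gpr": "", "subsystem": "exchange"},
    {"id": "R1", "name": "A to B", "stoichiometry": {"A_c": -1, "B_c": 1},
     "lb": 0, "ub": 1000, "reversible": false, "gpr": "g1", "subsystem": "toy pathway"},
    {"id": "R2", "name": "B to C", "stoichiometry": {"B_c": -1, "C_c": 1},
     "lb": 0, "ub": 1000, "reversible": false, "gpr": "(g1 and g2)", "subsystem": "toy pathway"},
    {"id": "SINK_C", "name": "C sink", "stoichiometry": {"C_c": -1},
     "lb": 0, "ub": 1000, "reversible": false, "gpr": "", "subsystem": "exchange"}
  ],
  "genes": ["g1", "g2"],
  "objective": {"biomass": "SINK_C", "atp": null, "weights": [1]}
}
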