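# Curated equivalence classes of annotation strings for the semantic
# consistency check. Each group lists names judged biologically equivalent;
# matching is case- and whitespace-insensitive. Extend per project.
- ["phage tail protein", "minor tail protein"]
- ["DNA polymerase III subunit epsilon", "DnaQ-like DNA polymerase III subunit"]
- ["terminase large subunit", "phage terminase, large subunit"]
- ["major capsid protein", "phage capsid protein"]
- ["lysin A", "endolysin"]
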