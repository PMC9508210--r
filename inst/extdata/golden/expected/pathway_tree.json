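{"name":"treated","count":12,"children":[{"name":"SNRI","count":1,"children":[{"name":"SSRI","count":1,"children":[]}]},{"name":"SSRI","count":1,"children":[{"name":"anxiolytic","count":1,"children":[]}]},{"name":"antipsychotic+atypical_antipsychotic","count":1,"children":[]},{"name":"behavioral_therapy","count":4,"children":[{"name":"SSRI","count":1,"children":[]},{"name":"centrally_acting_sympathomimetic","count":2,"children":[{"name":"imidazoline_agonist","count":1,"children":[]}]}]},{"name":"behavioral_therapy+centrally_acting_sympathomimetic","count":2,"children":[{"name":"SSRI","count":1,"children":[]}]},{"name":"centrally_acting_sympathomimetic+imidazoline_agonist","count":1,"children":[{"name":"anticonvulsant","count":1,"children":[]}]},{"name":"hypnotic_sedative","count":1,"children":[{"name":"anticonvulsant","count":1,"children":[]}]},{"name":"imidazoline_agonist","count":1,"children":[{"name":"behavioral_therapy","count":1,"children":[]}]}]}
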