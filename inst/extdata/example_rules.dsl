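# Thrombolysis-style exclusion rules, authored in the trialscreen DSL.
# Compile with:  trialscreen compile --dsl example_rules.dsl --out rules.json
trial "DSL example"
version "1"
exclusion "Platelet count below 100,000": lab "Platelets" < 100000
exclusion "APTT above 1.4 times control within 7 days":
    lab "APTT" > 1.4 x control within 7 days before index
exclusion "Headache or head injury within 3 years":
    (concept "Headache" in [outpatient note, admission note] within 3 years before index)
    or (concept "Head injury" in [outpatient note, admission note] within 3 years before index)
exclusion "History of diabetes with prior stroke":
    (concept "Diabetes mellitus" in [outpatient note, admission note, discharge summary])
    and (concept "Stroke" in [outpatient note, admission note, discharge summary])
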