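pattern,replacement,note
"^([a-z]{3,})ies$","\1y","plural -ies (parties -> party)"
"^([a-z]{2,})sses$","\1ss","plural -sses (classes stays class)"
"^([a-z]{2,}(?:ch|sh|x|z))es$","\1","plural -es after sibilant (wishes -> wish)"
"^([a-z]{2,}[^sui])s$","\1","plural -s except -ss/-us/-is (cravings -> craving)"
"^([a-z]{2,}?([bdfglmnprt]))\2ing$","\1","-ing with consonant doubling undone (quitting -> quit)"
"^([a-z]{5,})ing$","\1","-ing on long stems only (drinking -> drink; craving kept)"
"^([a-z]{2,}?([bdfglmnprt]))\2ed$","\1","-ed with consonant doubling undone (stopped -> stop)"
"^([a-z]{4,})ed$","\1","-ed on stems of 4+ (triggered -> trigger; tired kept)"
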