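group,category,term
substance,nicotine,nicotine
substance,nicotine,smoking
substance,nicotine,smoke
substance,nicotine,cigarette
substance,nicotine,cigarettes
substance,nicotine,tobacco
substance,nicotine,vape
substance,nicotine,vaping
substance,nicotine,cig
substance,nicotine,cigs
mental_health,depression,depression
mental_health,depression,depressed
mental_health,depression,depressive
mental_health,anxiety,anxiety
mental_health,anxiety,anxious
mental_health,anxiety,panic
mental_health,anxiety,panicking
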