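feature,domain
environmental_1,environmental
environmental_2,environmental
environmental_3,environmental
personality_1,personality
personality_2,personality
personality_3,personality
mental_health_1,mental_health
mental_health_2,mental_health
mental_health_3,mental_health
neurocognitive_1,neurocognitive
neurocognitive_2,neurocognitive
neurocognitive_3,neurocognitive
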