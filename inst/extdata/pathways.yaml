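# Quinone and haem biosynthesis pathway definitions.
# Each pathway is an ordered list of gene slots; a slot is satisfied by a
# retained similarity hit to any of its member genes, so slash pairs such as
# ubiD/ubiX count as a single slot.
pathways:
  ubiquinone:
    - [ubiC]
    - [ubiA]
    - [ubiD, ubiX]
    - [ubiB]
    - [ubiH]
    - [ubiE]
    - [ubiF]
    - [ubiG]
  menaquinone_alternative:
    - [MqnA]
    - [MqnB]
    - [MqnC]
    - [MqnD]
  menaquinone_classical:
    - [MenF]
    - [MenD]
    - [MenH]
    - [MenC]
    - [MenE]
    - [MenB]
    - [MenA]
    - [UbiE, MenG]
  haem_classical:
    - [HemE]
    - [HemF, HemN]
    - [HemY, HemG]
    - [HemH]
  haem_alternative:
    - [AhbA]
    - [AhbB]
    - [AhbC]
    - [AhbD]
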