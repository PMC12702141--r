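[
  {"stage": "tokens", "pattern": "(?i)(?<![a-z])neunac", "replacement": "Neu5Ac"},
  {"stage": "tokens", "pattern": "(?i)(?<![a-z])neuac", "replacement": "Neu5Ac"},
  {"stage": "tokens", "pattern": "(?i)(?<![a-z])nana(?![a-z])", "replacement": "Neu5Ac"},
  {"stage": "tokens", "pattern": "(?i)(?<![a-z])neungc", "replacement": "Neu5Gc"},
  {"stage": "tokens", "pattern": "(?i)(?<![a-z])neugc", "replacement": "Neu5Gc"},
  {"stage": "tokens", "pattern": "Neup5Ac", "replacement": "Neu5Ac"},
  {"stage": "tokens", "pattern": "Neup5Gc", "replacement": "Neu5Gc"},
  {"stage": "tokens", "pattern": "(?i)(?<![a-z])glcpnac", "replacement": "GlcNAc"},
  {"stage": "tokens", "pattern": "(?i)(?<![a-z])galpnac", "replacement": "GalNAc"},
  {"stage": "tokens", "pattern": "(?i)(?<![a-z])manpnac", "replacement": "ManNAc"},
  {"stage": "tokens", "pattern": "(?i)(?<![a-z])fucpnac", "replacement": "FucNAc"},
  {"stage": "tokens", "pattern": "(?i)(?<![a-z])glcpa(?![a-z])", "replacement": "GlcA"},
  {"stage": "tokens", "pattern": "(?i)(?<![a-z])galpa(?![a-z])", "replacement": "GalA"},
  {"stage": "tokens", "pattern": "(?i)(?<![a-z])idopa(?![a-z])", "replacement": "IdoA"},
  {"stage": "tokens", "pattern": "(?i)-ome$", "replacement": "-OMe"},
  {"stage": "tokens", "pattern": "-onl?$", "replacement": "-ol"},
  {"stage": "modifications", "pattern": "([A-Za-z])\\?(PCho|PEtn|PGro|Pyr|Ac|Am|Fo|Me|S|P)(?![a-z])", "replacement": "\\1O\\2"}
]
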