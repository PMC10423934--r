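[
  {
    "name": "all pups retrieved and grouped",
    "kind": "chunk_scored",
    "value_domain": "binary",
    "description": "every pup has been carried back and lies grouped in the nest"
  },
  {
    "name": "all pups nested",
    "kind": "chunk_scored",
    "value_domain": "binary",
    "description": "every pup is inside the nest"
  },
  {
    "name": "pup retrieval",
    "kind": "chunk_scored",
    "value_domain": "binary",
    "description": "dam carries a displaced pup back toward the nest"
  },
  {
    "name": "pup interaction",
    "kind": "chunk_scored",
    "value_domain": "binary",
    "description": "sniffing or anogenital licking of pups"
  },
  {
    "name": "crouching over pups",
    "kind": "chunk_scored",
    "value_domain": "binary",
    "description": "dam crouches in nursing posture over pups"
  },
  {
    "name": "resting with pups",
    "kind": "chunk_scored",
    "value_domain": "binary",
    "description": "dam rests in contact with pups"
  },
  {
    "name": "nest building",
    "kind": "chunk_scored",
    "value_domain": "binary",
    "description": "dam manipulates nesting material"
  },
  {
    "name": "solo activity",
    "kind": "chunk_scored",
    "value_domain": "binary",
    "description": "locomotion/exploration away from pups"
  },
  {
    "name": "solo rest",
    "kind": "chunk_scored",
    "value_domain": "binary",
    "description": "resting away from pups"
  },
  {
    "name": "latency to initiate retrieval",
    "kind": "whole_video",
    "value_domain": "seconds",
    "description": "seconds from assay start to first retrieval, censored at cutoff"
  },
  {
    "name": "latency to complete retrieval",
    "kind": "whole_video",
    "value_domain": "seconds",
    "description": "seconds from assay start to last pup grouped, censored at assay end"
  },
  {
    "name": "nest score",
    "kind": "whole_video",
    "value_domain": "ordinal_0_4",
    "description": "ordinal nest quality at assay end: 0 none .. 4 high structured walls"
  }
]
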