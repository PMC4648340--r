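{
  "_comment": "Plane-sequence orderings, fastest-varying axis first. The canonical ordering is omx (CPZAT). The zeiss and nikon entries are editable placeholders: verify the actual export ordering of your platform and edit accordingly, or pass an explicit order string.",
  "omx": "CPZAT",
  "zeiss": "PZCAT",
  "nikon": "PCZAT"
}
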