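# Posterior-to-anterior electrode axes per recording template.
# Channel lists are ordered posterior first; this order is authoritative for
# the axis stack, montage file order is not.
ds1:
  midline:
    channels: [Oz, Pz, Cz, Fz]
  left:
    channels: [O1, PO7, P7, CP5, FC5, F7]
  right:
    channels: [O2, PO8, P8, CP6, FC6, F8]
ds2:
  midline:
    # Corrected listing: the source montage table prints the midline with a
    # repeated "Fz", which cannot be a valid axis; Pz is the plausible reading.
    channels: [POz, Pz, Cz, Fz]
  midline_literal:
    # The listing exactly as printed (reversed to posterior-first). Contains a
    # duplicate label and is provided for transparency only, never as default.
    channels: [POz, Fz, Cz, Fz]
  left:
    channels: [O1, PO3, P3, C3, F3]
  right:
    channels: [O2, PO4, P4, C4, F4]
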