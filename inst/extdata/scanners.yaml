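# Example per-scanner configuration: couch water-equivalent area (cm^2,
# from contouring the table once per scanner) and the padding sentinel
# threshold (HU) used when normalizing that scanner's images.
CT11:
  table_aw_cm2: 56.5
  padding_sentinel: -1500
CT14:
  table_aw_cm2: 61.2
  padding_sentinel: -1500
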