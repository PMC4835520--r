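# Stringency presets for the five-parameter false-positive filters.
# A call is removed when any condition fails: GQ < gq_min, FDP < fdp_min,
# QUAL < qual_min, FAO < fao_min, and STB > stb_max (SNPs) or
# HRUN > hrun_max (indels). target_retention is the fraction of true
# positives each preset is designed to retain.

indel.low.gq_min = 5
indel.low.fdp_min = 10
indel.low.qual_min = 20
indel.low.hrun_max = 6
indel.low.fao_min = 4
indel.low.target_retention = 0.99

indel.medium.gq_min = 8
indel.medium.fdp_min = 20
indel.medium.qual_min = 30
indel.medium.hrun_max = 5
indel.medium.fao_min = 4
indel.medium.target_retention = 0.95

indel.high.gq_min = 10
indel.high.fdp_min = 25
indel.high.qual_min = 40
indel.high.hrun_max = 4
indel.high.fao_min = 4
indel.high.target_retention = 0.90

snp.low.gq_min = 5
snp.low.fdp_min = 6
snp.low.qual_min = 20
snp.low.stb_max = 0.90
snp.low.fao_min = 2
snp.low.target_retention = 0.99

snp.medium.gq_min = 10
snp.medium.fdp_min = 6
snp.medium.qual_min = 20
snp.medium.stb_max = 0.70
snp.medium.fao_min = 2
snp.medium.target_retention = 0.95

snp.high.gq_min = 15
snp.high.fdp_min = 10
snp.high.qual_min = 30
snp.high.stb_max = 0.60
snp.high.fao_min = 2
snp.high.target_retention = 0.90
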