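# Published summary counts from a resequenced 750-accession soybean
# germplasm panel (127 wild accessions WA, 424 landraces LR, 199 released
# cultivars RC): the worked-example inputs for the summarisation, binning,
# rate and chaining operations. All derived figures in the acceptance
# checks are recomputed from these counts at run time.
allele_universe: 559611
locus_universe: 154088
transitions:
  domestication:
    parent: WA
    child: LR
    years: 5000
    counts:
      inherited_fixed: 37
      inherited_LPD: 23670
      inherited_LPE: 2351
      inherited_increase: 206020
      inherited_decrease: 212521
      excluded: 76866
      emerged: 37543
      absent_both: 603
  modern_breeding:
    parent: LR
    child: RC
    years: 100
    sources: [WA]
    counts:
      inherited_fixed: 22261
      inherited_LPD: 23971
      inherited_LPE: 37
      inherited_LPR: 1409
      inherited_increase: 175203
      inherited_decrease: 179688
      excluded: 79573
      emerged: 603
      restored: 6238
      absent_both: 70628
# successive-change tallies across WA -> LR -> RC
chains:
  excluded_domestication_absent_rc: 70628   # of 76866 excluded in WA->LR
  excluded_domestication_restored_rc: 6238
  emerged_domestication_inherited_rc: 35690 # of 37543 emerged in WA->LR
  excluded_breeding_after_decrease: 75446   # of 79573 excluded in LR->RC
  fixed_breeding_after_increase: 23571      # of 23971 fixed (LPD) in LR->RC
  fixed_kept_through_breeding: 22261        # loci fixed in LR and in RC
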