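# one seeded synthetic-recovery run: plant a dimer, derive the three
# tightest true crosslink restraints, dock/filter/refine/select at
# routine reduced grid settings, and score the selected model against
# the planted truth (swap-aware ligand RMSD, orientation label)
recover_seed <- function(seed) {
  spec <- toy_spec(seed = seed)
  mono <- make_toy_monomer(spec)
  tru <- make_true_dimer(mono, seed = seed)
  tp <- tru$true_pairs[order(tru$true_pairs$distance), ]
  rs <- lapply(seq_len(min(3, nrow(tp))), function(i)
    restraint(tp$site1[i], tp$site2[i],
              max_distance = toy_crosslinker()$max_site_distance,
              origin = paste0(tp$site1[i], "-", tp$site2[i])))
  fit <- fit_dimer(mono$model, mono$model, rs,
                   spacing = 2.0, angle_step = 30, keep = 10000,
                   keep_per_rotation = 24, refine_top = 20,
                   compute_interface = FALSE)
  if (fit$status != "ok")
    return(list(ok = FALSE, rmsd = NA_real_, label_match = NA))
  sw <- dimer_complex(tru$complex$B, tru$complex$A)
  lr <- min(ligand_rmsd(fitted(fit), tru$complex),
            ligand_rmsd(fitted(fit), sw))
  lab <- classify_orientation(fitted(fit))$label
  list(ok = TRUE, rmsd = lr, label_match = lab == tru$orientation)
}
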