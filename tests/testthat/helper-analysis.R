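# Analysis helpers for the simulated breeding programmes.

# Rebase a multi-tier run at its base generation, standardize true
# breeding values there, partition by tier-gender and return, per tier
# and trait, the within-tier genetic gain (final minus base mean) and
# each path's partial trend over the same span.
multitier_trends <- function(mt, base_gen = 5L) {
  reb <- set_base(mt, mt$time >= base_gen)
  reb <- standardize_bv(reb, c("Tbv1", "Tbv2"), base_time = base_gen)
  p <- partition(reb)
  fin <- max(reb$time)
  out <- list()
  for (tier in c("nucleus", "multiplier")) {
    sm <- summarize_partition(p, "time", subset = reb$Tier == tier)
    for (tr in c("Tbv1", "Tbv2")) {
      d <- sm[[tr]]
      f <- d[d$time == base_gen, ]
      l <- d[d$time == fin, ]
      out[[paste(tier, tr, sep = ".")]] <-
        c(gain = l$Sum - f$Sum, unlist(l[p$info$lP]) - unlist(f[p$info$lP]))
    }
  }
  out
}

# per-generation mean path partitions of Population 1 individuals after
# rebasing the import scenario at the first import generation
import_pop1_trends <- function(seed, import_start = 11L) {
  imp <- simulate_import_example(import_config(seed = seed))
  reb <- set_base(imp, imp$time >= import_start)
  p <- partition(reb)
  sm <- summarize_partition(p, "time", subset = reb$Population == "Pop1")
  as.matrix(sm$Bv[, c("Pop1", "Pop2", "Pop3")])
}
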