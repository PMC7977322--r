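# Shared fixtures and oracles, all built in code.

# the published three-individual example: two founders from different
# populations and their offspring
trio_ped <- function() {
  ped_table(data.frame(
    id = c("75165", "76300", "83134"),
    sire = c(NA, NA, "76300"),
    dam = c(NA, NA, "75165"),
    time = c(0L, 0L, 1L),
    Population = c("Pop1", "Pop2", "Pop1"),
    Bv = c(9.20, 12.16, 10.42),
    stringsAsFactors = FALSE))
}

# partition columns of one trait as a plain matrix (input row order)
part_matrix <- function(p, trait) {
  as.matrix(p[[trait]][, paste0(trait, "_", p$info$lP), drop = FALSE])
}

# dense generalized-least-squares oracle for the animal model, using the
# no-inbreeding relationship matrix A = T D T' implied by the same
# founder/non-founder rules the sparse solver inverts
gls_oracle <- function(ped, trait, h2) {
  sp <- validate_and_sort(as_ped_table(ped))
  n <- nrow(sp)
  si <- match(sp$sire, sp$id, nomatch = 0L)
  di <- match(sp$dam, sp$id, nomatch = 0L)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (si[i] > 0) P[i, si[i]] <- 0.5
    if (di[i] > 0) P[i, di[i]] <- 0.5
  }
  Tm <- solve(diag(n) - P)
  D <- diag(1 - 0.25 * ((si > 0) + (di > 0)))
  A <- Tm %*% D %*% t(Tm)
  obs <- which(!is.na(sp[[trait]]))
  y <- sp[[trait]][obs]
  V <- h2 * A[obs, obs] + (1 - h2) * diag(length(obs))
  Vi <- solve(V)
  X <- matrix(1, length(obs), 1)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  ahat <- as.numeric(h2 * A[, obs] %*% Vi %*% (y - X %*% beta))
  ahat[match(as_ped_table(ped)$id, sp$id)]
}
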