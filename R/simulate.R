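## run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## multivariate normal draws given a covariance matrix (n x k)
rmvn <- function(n, Sigma) {
  k <- ncol(Sigma)
  matrix(stats::rnorm(n * k), n, k) %*% chol(Sigma)
}

#' Random pedigree fixtures under the infinitesimal model
#'
#' Generates an acyclic pedigree with known true breeding values for
#' property testing: founders draw `bv ~ N(0, sigma2_a)` and
#' non-founders follow `bv = 1/2 bv_s + 1/2 bv_d + w` with Mendelian
#' sampling deviations `w ~ N(0, sigma2_a / 2)` (non-inbred parents
#' assumed). Traits are independent. Path labels `P1..Pk` are assigned
#' at random. A small fraction of parent links is left unknown so that
#' founder and missing-parent handling is exercised. Output is
#' deterministic for a fixed seed.
#'
#' @param n number of individuals.
#' @param n_paths number of path labels.
#' @param n_traits number of independent traits (`bv1`, `bv2`, ...).
#' @param seed integer seed.
#' @param founder_frac fraction of records that are founders.
#' @param missing_parent_prob probability a non-founder parent link is
#'   unknown.
#' @param parent_mode parental semantics of the generated table; the
#'   second parental column is filled the same way in both modes, only
#'   its interpretation downstream changes.
#' @param sigma2_a additive-genetic variance per trait.
#' @return A [ped_table()] with `path_column = "path"` and
#'   `trait_columns = c("bv1", ...)` attributes set.
#' @export
generate_random_pedigree <- function(n, n_paths = 2L, n_traits = 1L,
                                     seed = 1L, founder_frac = 0.2,
                                     missing_parent_prob = 0.05,
                                     parent_mode = c("sire-dam", "sire-mgs"),
                                     sigma2_a = 1) {
  stopifnot(n >= 1, n_paths >= 1, n_traits >= 1)
  parent_mode <- match.arg(parent_mode)
  with_seed(seed, {
    nf <- max(min(2L, n), as.integer(round(founder_frac * n)))
    sex <- sample(rep_len(c("M", "F"), n))
    sire <- rep(NA_character_, n)
    dam <- rep(NA_character_, n)
    time <- integer(n)
    ids <- as.character(seq_len(n))
    bv <- matrix(0, n, n_traits)
    males <- integer(0)
    females <- integer(0)
    for (i in seq_len(n)) {
      founder <- i <= nf
      s <- d <- NA_integer_
      if (!founder) {
        if (length(males) > 0L && stats::runif(1) > missing_parent_prob) {
          s <- males[sample.int(length(males), 1L)]
        }
        if (length(females) > 0L && stats::runif(1) > missing_parent_prob) {
          d <- females[sample.int(length(females), 1L)]
        }
      }
      sire[i] <- if (is.na(s)) NA_character_ else ids[s]
      dam[i] <- if (is.na(d)) NA_character_ else ids[d]
      ptimes <- c(if (!is.na(s)) time[s], if (!is.na(d)) time[d])
      time[i] <- if (length(ptimes) == 0L) 0L else max(ptimes) + 1L
      if (is.na(s) && is.na(d)) {
        bv[i, ] <- stats::rnorm(n_traits, 0, sqrt(sigma2_a))
      } else {
        pa <- 0.5 * (if (is.na(s)) 0 else bv[s, ]) +
          0.5 * (if (is.na(d)) 0 else bv[d, ])
        bv[i, ] <- pa + stats::rnorm(n_traits, 0, sqrt(sigma2_a / 2))
      }
      if (sex[i] == "M") males <- c(males, i) else females <- c(females, i)
    }
    df <- data.frame(id = ids, sire = sire, dam = dam, time = time,
                     sex = sex,
                     path = paste0("P", sample.int(n_paths, n, replace = TRUE)),
                     stringsAsFactors = FALSE)
    traits <- paste0("bv", seq_len(n_traits))
    for (t in seq_len(n_traits)) df[[traits[t]]] <- bv[, t]
    ped <- ped_table(df, parent_mode = parent_mode)
    attr(ped, "path_column") <- "path"
    attr(ped, "trait_columns") <- traits
    ped
  })
}

#' Configuration of the three-population import scenario
#'
#' A small population (Population 1) selects males on own-population
#' phenotype with moderate accuracy; two larger populations achieve
#' faster gain through higher accuracy (heritability 0.9 vs 0.7) and,
#' for Population 3, higher male selection intensity (fewer sires
#' selected). The trait recorded for the analysis is Population 1's
#' trait; its genetic correlations with the traits under selection in
#' Populations 2 and 3 are 0.9 and 0.8 (genotype-by-environment
#' interaction). From `import_start` on, Population 1 sires each
#' offspring with semen imported from Populations 2 and 3 with the
#' given probabilities.
#'
#' @param seed integer seed.
#' @param n_generations total generations simulated.
#' @param import_start first generation in which Population 1 imports.
#' @param n_progeny progeny born per population per generation.
#' @param n_sires number of sires selected per population (named
#'   `Pop1`..`Pop3`; the smaller Population 3 count emulates its higher
#'   selection intensity).
#' @param h2 heritability of the selection trait in each population.
#' @param import_frac probability that a Population 1 offspring has a
#'   `Pop2` / `Pop3` sire during the import period.
#' @param genetic_cor correlations of Population 1's trait with the
#'   Population 2 and Population 3 traits.
#' @return A config list for [simulate_import_example()].
#' @export
import_config <- function(seed = 1L, n_generations = 20L, import_start = 11L,
                          n_progeny = 200L,
                          n_sires = c(Pop1 = 8L, Pop2 = 8L, Pop3 = 5L),
                          h2 = c(Pop1 = 0.7, Pop2 = 0.9, Pop3 = 0.9),
                          import_frac = c(Pop2 = 0.1, Pop3 = 0.1),
                          genetic_cor = c(Pop2 = 0.9, Pop3 = 0.8)) {
  stopifnot(all(import_frac >= 0), sum(import_frac) <= 1,
            all(h2 > 0 & h2 < 1), n_generations >= 2,
            import_start >= 2, all(n_sires >= 1))
  G <- diag(3)
  G[1, 2] <- G[2, 1] <- genetic_cor[[1]]
  G[1, 3] <- G[3, 1] <- genetic_cor[[2]]
  G[2, 3] <- G[3, 2] <- genetic_cor[[1]] * genetic_cor[[2]]
  list(seed = seed, n_generations = n_generations,
       import_start = import_start, n_progeny = n_progeny,
       n_sires = n_sires, h2 = h2, import_frac = import_frac, G = G)
}

#' Simulate a breeding programme importing genetic material
#'
#' Three populations under 20 generations of within-population male
#' selection on phenotype; in the import period Population 1 also uses
#' semen from Populations 2 and 3 (see [import_config()]). Breeding
#' values follow the multivariate infinitesimal model with Mendelian
#' covariance `G/2`. The emitted breeding-value column `Bv` is the
#' trait expressed in Population 1 for every individual; the path
#' column `Population` records each animal's population of origin.
#'
#' @param config list from [import_config()].
#' @return A [ped_table()] with columns `id`, `sire`, `dam`, `time`
#'   (generation), `Population`, `Sex` and `Bv`.
#' @export
simulate_import_example <- function(config = import_config()) {
  pops <- c("Pop1", "Pop2", "Pop3")
  with_seed(config$seed, {
    np <- config$n_progeny
    recs <- list()
    counter <- 0L
    new_ids <- function(k) {
      ids <- as.character(counter + seq_len(k))
      counter <<- counter + k
      ids
    }
    ## founders, generation 1
    gen_prev <- list()
    for (k in 1:3) {
      bv <- rmvn(np, config$G)
      gen_prev[[pops[k]]] <- data.frame(
        id = new_ids(np), sire = NA_character_, dam = NA_character_,
        time = 1L, Population = pops[k],
        Sex = sample(rep_len(c("M", "F"), np)),
        stringsAsFactors = FALSE)
      gen_prev[[pops[k]]]$bv <- bv
    }
    recs <- gen_prev
    for (g in 2:config$n_generations) {
      sel_males <- list()
      for (k in 1:3) {
        prev <- gen_prev[[pops[k]]]
        males <- prev[prev$Sex == "M", , drop = FALSE]
        ## phenotype of the population's own trait
        noise_sd <- sqrt((1 - config$h2[[k]]) / config$h2[[k]])
        phen <- males$bv[, k] + stats::rnorm(nrow(males), 0, noise_sd)
        top <- order(-phen, males$id)[seq_len(min(config$n_sires[[k]],
                                                  nrow(males)))]
        sel_males[[pops[k]]] <- males[top, , drop = FALSE]
      }
      gen_new <- list()
      importing <- g >= config$import_start
      for (k in 1:3) {
        prev <- gen_prev[[pops[k]]]
        dams <- prev[prev$Sex == "F", , drop = FALSE]
        di <- sample.int(nrow(dams), np, replace = TRUE)
        ## sire population of each offspring
        sire_pop <- rep(pops[k], np)
        if (k == 1L && importing) {
          u <- stats::runif(np)
          f2 <- config$import_frac[["Pop2"]]
          f3 <- config$import_frac[["Pop3"]]
          sire_pop[u < f2] <- "Pop2"
          sire_pop[u >= f2 & u < f2 + f3] <- "Pop3"
        }
        si <- integer(np)
        sire_id <- character(np)
        bv_s <- matrix(0, np, 3)
        for (sp in unique(sire_pop)) {
          rows <- which(sire_pop == sp)
          pool <- sel_males[[sp]]
          pick <- sample.int(nrow(pool), length(rows), replace = TRUE)
          sire_id[rows] <- pool$id[pick]
          bv_s[rows, ] <- pool$bv[pick, , drop = FALSE]
        }
        w <- rmvn(np, config$G / 2)
        bv <- 0.5 * bv_s + 0.5 * dams$bv[di, , drop = FALSE] + w
        gen_new[[pops[k]]] <- data.frame(
          id = new_ids(np), sire = sire_id, dam = dams$id[di],
          time = g, Population = pops[k],
          Sex = sample(rep_len(c("M", "F"), np)),
          stringsAsFactors = FALSE)
        gen_new[[pops[k]]]$bv <- bv
      }
      recs <- c(recs, gen_new)
      gen_prev <- gen_new
    }
    all <- do.call(rbind, recs)
    df <- all[, c("id", "sire", "dam", "time", "Population", "Sex")]
    df$Bv <- all$bv[, 1]  # the trait expressed in Population 1
    ped <- ped_table(df)
    attr(ped, "path_column") <- "Population"
    attr(ped, "trait_columns") <- "Bv"
    ped
  })
}

#' Configuration of the two-tier nucleus/multiplier programme
#'
#' A closed nucleus selects males and females on an equal-weight index
#' of two traits; a multiplier tier multiplies nucleus genetics. Trait
#' 1 (h2 = 0.25) is measured in both tiers, trait 2 (h2 = 0.10) only in
#' the nucleus. During burn-in only the nucleus exists and selection is
#' on a phenotype index; in the evaluation period selection is on an
#' index of estimated breeding values from pedigree BLUP fitted to all
#' data from the base generation onward. Multiplier sires are either
#' all nucleus males (`maleflow100`) or a mix of nucleus and multiplier
#' males (`maleflow20`, where nucleus males make up ~20% of the sire
#' set). `random` replaces every ranking by a random one (a null
#' scenario under which no path should show a partial trend).
#'
#' Default sizes are a 1/10 desk scale of a stylised pig programme;
#' `paper_scale = TRUE` restores the full sizes (25/500/6000 nucleus,
#' 750/9000 multiplier, 100 multiplier males, 5000 seed females, 20+20
#' generations).
#'
#' @param seed integer seed.
#' @param scenario `"maleflow100"`, `"maleflow20"` or `"random"`.
#' @param n_burnin,n_eval burn-in and evaluation generation counts.
#' @param nucleus_males,nucleus_females,nucleus_progeny nucleus tier
#'   sizes per generation.
#' @param multiplier_females,multiplier_progeny multiplier tier sizes.
#' @param multiplier_males multiplier males selected under
#'   `maleflow20`.
#' @param seed_females females generated from nucleus matings in the
#'   last burn-in generation to seed the multiplier.
#' @param h2 heritabilities of the two traits.
#' @param paper_scale use full published sizes instead of desk scale.
#' @return A config list for [simulate_multitier()].
#' @export
multitier_config <- function(seed = 1L,
                             scenario = c("maleflow100", "maleflow20", "random"),
                             n_burnin = 5L, n_eval = 10L,
                             nucleus_males = 10L, nucleus_females = 100L,
                             nucleus_progeny = 600L,
                             multiplier_females = 150L,
                             multiplier_progeny = 900L,
                             multiplier_males = 40L,
                             seed_females = 500L,
                             h2 = c(0.25, 0.10),
                             paper_scale = FALSE) {
  scenario <- match.arg(scenario)
  if (paper_scale) {
    n_burnin <- 20L; n_eval <- 20L
    nucleus_males <- 25L; nucleus_females <- 500L; nucleus_progeny <- 6000L
    multiplier_females <- 750L; multiplier_progeny <- 9000L
    multiplier_males <- 100L; seed_females <- 5000L
  }
  stopifnot(nucleus_males + nucleus_females <= nucleus_progeny,
            multiplier_females <= seed_females,
            all(h2 > 0 & h2 < 1), n_burnin >= 2, n_eval >= 1)
  list(seed = seed, scenario = scenario, n_burnin = n_burnin, n_eval = n_eval,
       nucleus_males = nucleus_males, nucleus_females = nucleus_females,
       nucleus_progeny = nucleus_progeny,
       multiplier_females = multiplier_females,
       multiplier_progeny = multiplier_progeny,
       multiplier_males = multiplier_males, seed_females = seed_females,
       h2 = h2)
}

#' Simulate a two-tier nucleus/multiplier breeding programme
#'
#' See [multitier_config()] for the design. True breeding values follow
#' the two-trait infinitesimal model (independent traits, additive
#' variance 1, Mendelian sampling variance 1/2, inbreeding ignored);
#' phenotypes add environmental noise with variance `(1 - h2) / h2`.
#' Estimated breeding values are refreshed before every selection
#' decision of the evaluation period by [estimate_breeding_values()]
#' fitted to all phenotypes recorded from the base generation (last
#' burn-in generation) onward.
#'
#' @param config list from [multitier_config()].
#' @return A [ped_table()] with columns `id`, `sire`, `dam`, `time`
#'   (generation), `Tier`, `Sex`, `TierGender` (path label such as
#'   `"nucleus-male"`), true breeding values `Tbv1`/`Tbv2`, phenotypes
#'   `Pheno1`/`Pheno2` (`Pheno2` is `NA` in the multiplier) and the
#'   latest estimated breeding values `Ebv1`/`Ebv2` (`NA` for
#'   generations never evaluated).
#' @export
simulate_multitier <- function(config = multitier_config()) {
  with_seed(config$seed, {
    h2 <- config$h2
    noise_sd <- sqrt((1 - h2) / h2)
    counter <- 0L
    born <- function(k, g, tier, sire, dam, tbv) {
      ids <- as.character(counter + seq_len(k))
      counter <<- counter + k
      sex <- sample(rep_len(c("M", "F"), k))
      df <- data.frame(id = ids, sire = sire, dam = dam, time = g,
                       Tier = tier, Sex = sex,
                       stringsAsFactors = FALSE)
      df$Tbv1 <- tbv[, 1]; df$Tbv2 <- tbv[, 2]
      df$Pheno1 <- tbv[, 1] + stats::rnorm(k, 0, noise_sd[1])
      df$Pheno2 <- tbv[, 2] + stats::rnorm(k, 0, noise_sd[2])
      df$Pheno2[df$Tier == "multiplier"] <- NA_real_  # trait 2 unmeasured there
      df$Ebv1 <- NA_real_; df$Ebv2 <- NA_real_
      df
    }
    mate <- function(sires, dams, n_prog, g, tier) {
      di <- rep(seq_len(nrow(dams)), length.out = n_prog)
      si <- sample.int(nrow(sires), n_prog, replace = TRUE)
      tbv <- 0.5 * as.matrix(sires[si, c("Tbv1", "Tbv2")]) +
        0.5 * as.matrix(dams[di, c("Tbv1", "Tbv2")]) +
        matrix(stats::rnorm(2L * n_prog, 0, sqrt(0.5)), n_prog, 2L)
      born(n_prog, g, tier, sires$id[si], dams$id[di], tbv)
    }
    seed_sex <- function(df, sex) { df$Sex <- sex; df }
    top_n <- function(df, score, k) {
      if (nrow(df) == 0L || k == 0L) return(df[0L, , drop = FALSE])
      df[order(-score, df$id)[seq_len(min(k, nrow(df)))], , drop = FALSE]
    }
    ## generation 1: nucleus founders
    founders <- born(config$nucleus_progeny, 1L, "nucleus",
                     NA_character_, NA_character_,
                     matrix(stats::rnorm(2L * config$nucleus_progeny),
                            ncol = 2L))
    recs <- list(founders)
    prev <- founders
    base_gen <- config$n_burnin
    n_total_gen <- config$n_burnin + config$n_eval
    for (g in 2:n_total_gen) {
      burnin <- g <= base_gen
      all_so_far <- NULL
      if (!burnin) {
        ## refresh EBVs from all data since the base generation
        all_so_far <- do.call(rbind, recs)
        evalped <- set_base(as_eval_ped(all_so_far),
                            all_so_far$time >= base_gen)
        if (config$scenario != "random") {
          e1 <- estimate_breeding_values(evalped, "Pheno1", h2[1])
          e2 <- estimate_breeding_values(evalped, "Pheno2", h2[2])
          eb <- data.frame(id = evalped$id, Ebv1 = e1, Ebv2 = e2,
                           stringsAsFactors = FALSE)
          m <- match(prev$id, eb$id)
          prev$Ebv1 <- eb$Ebv1[m]
          prev$Ebv2 <- eb$Ebv2[m]
          ## record the estimates on the emitted rows as well
          for (r in seq_along(recs)) {
            mm <- match(recs[[r]]$id, eb$id)
            upd <- !is.na(mm)
            recs[[r]]$Ebv1[upd] <- eb$Ebv1[mm[upd]]
            recs[[r]]$Ebv2[upd] <- eb$Ebv2[mm[upd]]
          }
        }
      }
      score <- function(df) {
        if (config$scenario == "random") return(stats::runif(nrow(df)))
        if (burnin) df$Pheno1 + df$Pheno2 else df$Ebv1 + df$Ebv2
      }
      nuc <- prev[prev$Tier == "nucleus", , drop = FALSE]
      nuc_m <- nuc[nuc$Sex == "M", , drop = FALSE]
      nuc_f <- nuc[nuc$Sex == "F", , drop = FALSE]
      if (nrow(nuc_m) < config$nucleus_males ||
          nrow(nuc_f) < config$nucleus_females) {
        stop("selected counts exceed available nucleus candidates in generation ",
             g)
      }
      sel_m <- top_n(nuc_m, score(nuc_m), config$nucleus_males)
      sel_f <- top_n(nuc_f, score(nuc_f), config$nucleus_females)
      gen_rows <- list(mate(sel_m, sel_f, config$nucleus_progeny, g, "nucleus"))
      if (g == base_gen) {
        ## seed the multiplier with females in the base generation
        seedf <- mate(sel_m, sel_f, config$seed_females, g, "multiplier")
        seedf <- seed_sex(seedf, "F")
        seedf$Pheno2 <- NA_real_
        gen_rows <- c(gen_rows, list(seedf))
      }
      if (g > base_gen) {
        mult <- prev[prev$Tier == "multiplier", , drop = FALSE]
        mult_f <- mult[mult$Sex == "F", , drop = FALSE]
        if (nrow(mult_f) < config$multiplier_females) {
          stop("selected counts exceed available multiplier females in generation ",
               g)
        }
        dams <- top_n(mult_f, score(mult_f), config$multiplier_females)
        sires <- sel_m
        if (config$scenario == "maleflow20") {
          mult_m <- mult[mult$Sex == "M", , drop = FALSE]
          if (nrow(mult_m) > 0L) {
            sires <- rbind(sel_m, top_n(mult_m, score(mult_m),
                                        config$multiplier_males))
          }
        }
        gen_rows <- c(gen_rows,
                      list(mate(sires, dams, config$multiplier_progeny, g,
                                "multiplier")))
      }
      newgen <- do.call(rbind, gen_rows)
      recs <- c(recs, list(newgen))
      prev <- newgen
    }
    out <- do.call(rbind, recs)
    out$TierGender <- paste(out$Tier, ifelse(out$Sex == "M", "male", "female"),
                            sep = "-")
    ped <- ped_table(out)
    attr(ped, "path_column") <- "TierGender"
    attr(ped, "trait_columns") <- c("Tbv1", "Tbv2")
    ped
  })
}

## minimal ped_table view used for in-simulation evaluation
as_eval_ped <- function(df) {
  ped_table(df[, c("id", "sire", "dam", "time", "Tier", "Pheno1", "Pheno2")])
}

#' Standardize breeding values to a base generation
#'
#' Centres and scales the given trait columns so that the base
#' generation has mean 0 and (genetic) standard deviation 1, the usual
#' presentation scale for partitioned trends.
#'
#' @param ped a [ped_table()].
#' @param trait_columns numeric columns to standardize.
#' @param base_time value of `time` defining the base generation.
#' @return The `ped_table` with transformed trait columns.
#' @export
standardize_bv <- function(ped, trait_columns, base_time) {
  ped <- as_ped_table(ped)
  base <- ped$time == base_time & !is.na(ped$time)
  if (!any(base)) stop("no records in base generation time = ", base_time)
  for (tr in trait_columns) {
    mu <- mean(ped[[tr]][base])
    sd0 <- stats::sd(ped[[tr]][base])
    if (!is.finite(sd0) || sd0 == 0) {
      stop("zero genetic variance in base generation for '", tr, "'")
    }
    ped[[tr]] <- (ped[[tr]] - mu) / sd0
  }
  ped
}
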