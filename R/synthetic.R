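# Synthetic molecule generator: multi-scaffold SMILES datasets with
# scaffold-dependent pIC50 levels, class imbalance and planted activity
# cliffs, plus the ground truth needed to validate every pipeline stage.

#' Default scaffold templates
#'
#' Hand-written generic frameworks (two steroid-like fused tetracyclics,
#' fused bicyclics, biaryls, saturated rings) with one or two numbered
#' attachment sites written as `{R1}` / `{R2}`. The templates emulate the
#' shape of a medicinal-chemistry dataset - they are not any specific
#' compound series.
#'
#' @return data.frame with columns `name`, `template`, `steroidal`.
#' @export
default_templates <- function() {
  data.frame(stringsAsFactors = FALSE, rbind(
    c("steroid_a",    "C1CC({R2})C2C1CCC1C2CCC2CC({R1})CCC21",  TRUE),
    c("steroid_b",    "C1CCCC2C1CCC1C2CCC2CC({R1})CC({R2})C21", TRUE),
    c("biphenyl",     "c1cc({R1})ccc1-c1cccc({R2})c1",          FALSE),
    c("phenylpyridine", "c1cc({R1})cnc1-c1ccc({R2})cc1",        FALSE),
    c("quinoline",    "c1cc({R2})c2nc({R1})ccc2c1",             FALSE),
    c("indole",       "c1cc({R2})c2[nH]c({R1})cc2c1",           FALSE),
    c("benzimidazole", "c1ccc2[nH]c({R1})nc2c1",                FALSE),
    c("naphthalene",  "c1cc({R2})c2cc({R1})ccc2c1",             FALSE),
    c("benzylpiperidine", "C1CCN(Cc2ccc({R1})cc2)CC1",          FALSE),
    c("imidazole_phenyl", "c1cn(-c2ccc({R1})cc2)cn1",           FALSE),
    c("benzothiazole", "c1ccc2sc({R1})nc2c1",                   FALSE),
    c("pyrimidine",   "c1cc({R1})ncn1",                         FALSE),
    c("morpholine_phenyl", "C1COCCN1c1ccc({R1})cc1",            FALSE),
    c("phenyl",       "c1ccc({R1})cc1",                         FALSE),
    c("tetralin",     "C1CCc2ccc({R1})cc2C1",                   FALSE),
    c("furan_phenyl", "c1cc(-c2ccc({R1})cc2)co1",               FALSE),
    c("pyrazole_phenyl", "c1cc({R1})n(-c2ccc({R2})cc2)n1",      FALSE),
    c("cyclohexyl",   "C1CCC({R1})CC1",                         FALSE)
  )) |> stats::setNames(c("name", "template", "steroidal")) |>
    transform(steroidal = as.logical(steroidal))
}

# Default substituent library: fragment SMILES (written as a branch off the
# attachment atom; "" is hydrogen) with additive pIC50 effects on the scale
# of typical R-group SAR increments.
default_rgroup_library <- function() {
  data.frame(stringsAsFactors = FALSE,
    substituent = c("", "C", "CC", "O", "N", "F", "Cl", "C(F)(F)F",
                    "OC", "C#N", "C(N)=O", "S(C)(=O)=O"),
    effect = c(0, 0.1, -0.1, 0.25, 0.15, 0.2, -0.2, 0.25,
               -0.25, 0, -0.15, 0.2))
}

# Large, well-separated substituent effects for the designated QSAR
# modeling scaffold: additive levels ~0/-1/-2/-3 place compounds near the
# centers of the four potency classes.
modeling_effects <- function() {
  stats::setNames(
    c(0, 0, 0.05, -0.05, 0, -0.95, -1, -1.95, -2, -2.95, -3, -1.05),
    c("", "C", "F", "N", "O", "OC", "CC", "Cl", "S(C)(=O)=O", "C#N",
      "C(N)=O", "C(F)(F)F"))
}

# Default per-scaffold baseline pIC50 levels: three all-active fused
# heteroaromatics, a potency gradient down to one all-inactive scaffold,
# and a frequency tail.
default_scaffold_base <- function() {
  c(steroid_a = 8.5, steroid_b = 8.3, biphenyl = 8.5,
    phenylpyridine = 6.9, quinoline = 8.6, indole = 8.4,
    benzimidazole = 8.2, naphthalene = 7.4, benzylpiperidine = 7.2,
    imidazole_phenyl = 6.6, benzothiazole = 6.4, pyrimidine = 6.2,
    morpholine_phenyl = 5.0, phenyl = 6.8, tetralin = 7.6,
    furan_phenyl = 7.1, pyrazole_phenyl = 6.3, cyclohexyl = 5.4)
}

default_n_per_scaffold <- function() {
  c(steroid_a = 45, steroid_b = 25, biphenyl = 45, phenylpyridine = 24,
    quinoline = 18, indole = 15, benzimidazole = 12, naphthalene = 15,
    benzylpiperidine = 12, imidazole_phenyl = 10, benzothiazole = 8,
    pyrimidine = 6, morpholine_phenyl = 12, phenyl = 8, tetralin = 5,
    furan_phenyl = 3, pyrazole_phenyl = 2, cyclohexyl = 1)
}

#' Synthetic dataset configuration
#'
#' Defines the generator's study conditions: scaffold templates, baseline
#' pIC50 per scaffold, the substituent library with additive effects
#' (optionally overridden per scaffold), observation noise, per-scaffold
#' compound counts and planted activity-cliff pairs.
#'
#' @param templates data.frame as [default_templates()].
#' @param scaffold_base named numeric, baseline pIC50 per scaffold.
#' @param rgroup_library data.frame `substituent`, `effect`.
#' @param effect_overrides named list: scaffold name -> named numeric of
#'   per-substituent effects replacing the library defaults.
#' @param n_per_scaffold named integer vector.
#' @param noise_sd Gaussian observation noise, pIC50 units (default 0.3,
#'   the scale of within-assay variability).
#' @param n_cliff_pairs planted same-scaffold cliff pairs (default 5).
#' @param cliff_scaffolds scaffolds that receive cliff pairs (one pair
#'   each, in order).
#' @param cliff_subs length-2 character: the substituent of the cliff
#'   pair's base member and of its variant (kept out of the regular
#'   library so planted molecules are unique).
#' @param cliff_effects effects of `cliff_subs`; their gap sets the planted
#'   true pIC50 difference (default 3.5).
#' @param seed integer seed (default 42).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(templates = default_templates(),
                             scaffold_base = default_scaffold_base(),
                             rgroup_library = default_rgroup_library(),
                             effect_overrides =
                               list(biphenyl = modeling_effects()),
                             n_per_scaffold = default_n_per_scaffold(),
                             noise_sd = 0.3,
                             n_cliff_pairs = 5,
                             cliff_scaffolds = c("steroid_a", "naphthalene",
                                                 "benzylpiperidine",
                                                 "phenylpyridine",
                                                 "tetralin"),
                             cliff_subs = c("CCC", "CCO"),
                             cliff_effects = c(-0.05, -3.55),
                             seed = 42) {
  stopifnot(noise_sd >= 0, n_cliff_pairs >= 0,
            all(names(scaffold_base) %in% templates$name),
            all(names(n_per_scaffold) %in% templates$name),
            all(cliff_scaffolds %in% templates$name),
            length(cliff_subs) == 2L, length(cliff_effects) == 2L)
  if (n_cliff_pairs > length(cliff_scaffolds))
    stop("n_cliff_pairs exceeds the number of cliff scaffolds",
         call. = FALSE)
  structure(list(templates = templates, scaffold_base = scaffold_base,
                 rgroup_library = rgroup_library,
                 effect_overrides = effect_overrides,
                 n_per_scaffold = n_per_scaffold, noise_sd = noise_sd,
                 n_cliff_pairs = n_cliff_pairs,
                 cliff_scaffolds = cliff_scaffolds,
                 cliff_subs = cliff_subs, cliff_effects = cliff_effects,
                 seed = seed),
            class = "synthetic_config")
}

# Instantiate a template with substituents; "" removes the branch.
fill_template <- function(template, subs) {
  out <- template
  for (i in seq_along(subs)) {
    token <- sprintf("({R%d})", i)
    repl <- if (nzchar(subs[i])) sprintf("(%s)", subs[i]) else ""
    out <- sub(token, repl, out, fixed = TRUE)
  }
  out
}

template_sites <- function(template) {
  length(gregexpr("\\{R[0-9]+\\}", template)[[1]])
}

#' Generate a synthetic compound dataset with ground truth
#'
#' Enumerates each scaffold template with substituent combinations drawn
#' seed-deterministically (without replacement; canonical-SMILES collisions
#' from symmetric sites are resampled). True pIC50 = scaffold baseline +
#' the sum of substituent effects; observed pIC50 adds Gaussian noise.
#' Activity-cliff pairs are injected as (base member, single-substituent
#' variant) with a large fixed true-pIC50 gap.
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (curated-format data.frame: `compound_id`,
#'   `smiles`, `ic50`, `pic50`, `activity_class`, `category`) and `truth`
#'   (list: `compounds` with scaffold assignment and noise-free pIC50,
#'   `scaffolds` with expected EF at threshold 7, `cliffs` with planted
#'   pair ids and true differences).
#' @export
generate_dataset <- function(config) {
  tpl <- config$templates
  lib <- config$rgroup_library
  names_used <- names(config$n_per_scaffold)

  rows <- list()
  with_seed(config$seed, {
    for (sc in names_used) {
      n_want <- config$n_per_scaffold[[sc]]
      if (n_want < 1) next
      template <- tpl$template[tpl$name == sc]
      if (length(template) != 1L)
        stop("unknown scaffold in n_per_scaffold: ", sc, call. = FALSE)
      k <- template_sites(template)
      effects <- lib$effect
      if (sc %in% names(config$effect_overrides)) {
        ov <- config$effect_overrides[[sc]]
        pos <- match(names(ov), lib$substituent)
        if (anyNA(pos))
          stop("effect override for unknown substituent(s): ",
               paste(names(ov)[is.na(pos)], collapse = ", "),
               call. = FALSE)
        effects[pos] <- ov
      }
      combos <- expand.grid(rep(list(lib$substituent), k),
                            stringsAsFactors = FALSE)
      if (nrow(combos) < n_want) {
        warning("scaffold '", sc, "': only ", nrow(combos),
                " substituent combinations; reducing from ", n_want)
        n_want <- nrow(combos)
      }
      order_pool <- sample(nrow(combos))
      seen <- character(0)
      taken <- 0L
      for (ci in order_pool) {
        if (taken >= n_want) break
        subs <- as.character(combos[ci, ])
        smi <- fill_template(template, subs)
        can <- canonical_smiles(smi)
        if (can %in% seen) next
        seen <- c(seen, can)
        taken <- taken + 1L
        rows[[length(rows) + 1L]] <- list(
          scaffold = sc, smiles = can,
          true_pic50 = config$scaffold_base[[sc]] +
            sum(effects[match(subs, lib$substituent)]),
          cliff = NA_integer_)
      }
      if (taken < n_want)
        warning("scaffold '", sc, "': symmetric collisions left only ",
                taken, " distinct molecules of ", n_want)
    }

    if (config$n_cliff_pairs > 0) {
      filler_effect <- lib$effect[match("C", lib$substituent)]
      for (pi in seq_len(config$n_cliff_pairs)) {
        sc <- config$cliff_scaffolds[pi]
        template <- tpl$template[tpl$name == sc]
        k <- template_sites(template)
        for (v in 1:2) {
          subs <- c(config$cliff_subs[v], rep("C", k - 1L))
          rows[[length(rows) + 1L]] <- list(
            scaffold = sc,
            smiles = canonical_smiles(fill_template(template, subs)),
            true_pic50 = config$scaffold_base[[sc]] +
              config$cliff_effects[v] + (k - 1L) * filler_effect,
            cliff = pi)
        }
      }
    }

    n <- length(rows)
    noise <- stats::rnorm(n, 0, config$noise_sd)
    df <- data.frame(stringsAsFactors = FALSE,
      compound_id = sprintf("SYN%04d", seq_len(n)),
      scaffold = vapply(rows, `[[`, character(1), "scaffold"),
      smiles = vapply(rows, `[[`, character(1), "smiles"),
      true_pic50 = vapply(rows, `[[`, numeric(1), "true_pic50"),
      cliff = vapply(rows, `[[`, integer(1), "cliff"))
    df$pic50 <- df$true_pic50 + noise
    if (anyDuplicated(df$smiles))
      stop("internal error: duplicate molecules across scaffolds",
           call. = FALSE)

    records <- data.frame(stringsAsFactors = FALSE,
      compound_id = df$compound_id, smiles = df$smiles,
      ic50 = 10^(-df$pic50), pic50 = df$pic50)
    records$activity_class <- assign_activity_class(records$pic50)
    steroidal <- tpl$steroidal[match(df$scaffold, tpl$name)]
    records$category <- factor(ifelse(steroidal, "steroidal",
                                      "nonsteroidal"),
                               levels = c("steroidal", "nonsteroidal",
                                          "unknown"))

    p_all <- mean(df$true_pic50 >= 7)
    scaff_truth <- do.call(rbind, lapply(split(df, df$scaffold),
      function(g) data.frame(stringsAsFactors = FALSE,
        scaffold = g$scaffold[1], n = nrow(g),
        base = config$scaffold_base[[g$scaffold[1]]],
        ef_true = if (p_all > 0) mean(g$true_pic50 >= 7) / p_all
                  else NA_real_)))
    rownames(scaff_truth) <- NULL

    cliffs <- do.call(rbind, lapply(
      split(df[!is.na(df$cliff), ], df$cliff[!is.na(df$cliff)]),
      function(g) data.frame(stringsAsFactors = FALSE,
        id_a = g$compound_id[1], id_b = g$compound_id[2],
        scaffold = g$scaffold[1],
        delta_true = abs(diff(g$true_pic50)))))
    if (is.null(cliffs))
      cliffs <- data.frame(id_a = character(0), id_b = character(0),
                           scaffold = character(0),
                           delta_true = numeric(0))
    rownames(cliffs) <- NULL

    list(records = records,
         truth = list(
           compounds = df[, c("compound_id", "scaffold", "true_pic50")],
           scaffolds = scaff_truth,
           cliffs = cliffs,
           active_proportion_true = p_all))
  })
}

#' Generate the standard synthetic benchmark fixture
#'
#' A ~280-compound dataset with 18 scaffolds, a frequency-rank tail
#' including singletons, four potency classes with the potent class
#' dominating the steroid-like subset, at least three all-active scaffolds,
#' one scaffold with no actives, and five planted activity-cliff pairs.
#'
#' @param seed integer seed.
#' @param noise_sd observation noise (default 0.3; use 0 for the noise-free
#'   variant with exactly recoverable ground truth).
#' @return list with `records` and `truth`, see [generate_dataset()].
#' @export
make_benchmark_fixture <- function(seed = 42, noise_sd = 0.3) {
  generate_dataset(synthetic_config(seed = seed, noise_sd = noise_sd))
}
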