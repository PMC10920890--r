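# mean of member probability matrices (or logit-space mean)
ensemble_mean <- function(prob_list, method = c("mean-prob", "mean-logit")) {
  method <- match.arg(method)
  if (method == "mean-prob") {
    out <- Reduce(`+`, prob_list) / length(prob_list)
  } else {
    lg <- Reduce(`+`, lapply(prob_list, log)) / length(prob_list)
    out <- exp(lg)
    out <- out / rowSums(out)
  }
  out
}

#' Ensemble prediction for voxel grids
#'
#' Averages the softmax outputs of several independently trained models
#' (arithmetic mean of probabilities by default, geometric/logit mean as an
#' option). A single-model ensemble returns that model's probabilities
#' unchanged.
#'
#' @param models A list of `resnet3d` models sharing the class order.
#' @param grids List of voxel arrays (or a single array).
#' @param method `"mean-prob"` (default) or `"mean-logit"`.
#' @return Probability matrix `(n_items, n_classes)`.
#' @export
ensemble_predict_grids <- function(models, grids,
                                   method = c("mean-prob", "mean-logit")) {
  if (inherits(models, "resnet3d")) models <- list(models)
  n_cls <- unique(vapply(models, function(m) m$config$n_classes, integer(1)))
  if (length(n_cls) != 1) stop("ensemble members disagree on class order/count")
  ensemble_mean(lapply(models, predict_proba, grids = grids), method)
}

#' Predict the amino-acid profile of one residue from a structure
#'
#' Runs the full path: extract the center-masked microenvironment, voxelize
#' it, and apply the model ensemble.
#'
#' @param structure An annotated `annotated_structure`.
#' @param models A `resnet3d` or list of them.
#' @param chain,residue_seq,insert Residue identity.
#' @param sampling A [sampling_config()].
#' @param voxel A [voxel_config()].
#' @param method Ensemble method, see [ensemble_predict_grids()].
#' @return A `prediction_profile`: list with `key`, `probabilities` (named
#'   20-vector), `interface_flag`, `interface_kind`.
#' @export
predict_residue_profile <- function(structure, models, chain, residue_seq,
                                    insert = "", sampling = sampling_config(),
                                    voxel = voxel_config(),
                                    method = "mean-prob") {
  env <- extract_microenvironment(structure, chain, residue_seq, insert, sampling)
  grid <- voxelize(env, voxel)
  p <- ensemble_predict_grids(models, list(grid), method = method)[1, ]
  structure(list(key = env$key, probabilities = p,
                 interface_flag = env$interface_flag,
                 interface_kind = env$interface_kind),
            class = "prediction_profile")
}

#' Log-odds mutation score
#'
#' `ln p(mutant) - ln p(wild type)` from a 20-way probability vector;
#' positive values are interpreted as stabilizing/favorable substitutions.
#'
#' @param profile A `prediction_profile` or a named/plain numeric 20-vector
#'   of probabilities in [aa_alphabet()] order.
#' @param wt_aa,mut_aa One- or three-letter amino-acid codes.
#' @return Scalar log-odds (natural log).
#' @export
log_odds <- function(profile, wt_aa, mut_aa) {
  p <- if (inherits(profile, "prediction_profile")) profile$probabilities else profile
  iw <- aa_index(wt_aa)
  im <- aa_index(mut_aa)
  if (is.na(iw) || is.na(im)) stop("unknown amino-acid code: ", wt_aa, " / ", mut_aa)
  log(p[[im]]) - log(p[[iw]])
}

#' Zero-shot benchmark of log-odds scores against experimental mutations
#'
#' Scores each mutation through the full featurize-predict-log-odds path and
#' correlates the scores with the experimental columns (`dTm` and/or `ddG`).
#' Rows whose wild-type code disagrees with the structure are skipped with a
#' message; correlations are reported as `NA` when fewer than 3 scorable
#' values exist.
#'
#' @param models A `resnet3d` or list of models.
#' @param structures Named list of annotated structures, keyed by the
#'   mutation table's `structure` column.
#' @param mutations Tibble/data frame with columns
#'   `structure, chain, position, wt, mut` and optionally `dTm`, `ddG`.
#' @param sampling,voxel Configurations for the featurization path.
#' @param profiles Optional precomputed profiles: named list keyed by
#'   `"<structure>|<chain>|<position>"`, each a 20-probability vector. When
#'   supplied the featurization path is bypassed (used by fixtures with
#'   planted profiles).
#' @return List of class `zero_shot_benchmark`: `scores` tibble (mutation
#'   rows plus `log_odds`), `correlations` tibble
#'   (`property`, `pearson`, `spearman`, `n`), `n_skipped`.
#' @export
zero_shot_benchmark <- function(models, structures, mutations,
                                sampling = sampling_config(),
                                voxel = voxel_config(), profiles = NULL) {
  mut <- tibble::as_tibble(mutations)
  need <- c("structure", "chain", "position", "wt", "mut")
  if (!all(need %in% names(mut))) {
    stop("mutation table needs columns ", paste(need, collapse = ", "))
  }
  scores <- rep(NA_real_, nrow(mut))
  skipped <- 0L
  cache <- list()
  for (i in seq_len(nrow(mut))) {
    key <- paste(mut$structure[i], mut$chain[i], mut$position[i], sep = "|")
    p <- NULL
    if (!is.null(profiles)) {
      p <- profiles[[key]]
    } else {
      if (is.null(cache[[key]])) {
        s <- structures[[mut$structure[i]]]
        if (is.null(s)) { skipped <- skipped + 1L; next }
        wt_in_structure <- s$atoms$residue_name[
          s$atoms$chain == mut$chain[i] & s$atoms$residue_seq == mut$position[i]][1]
        if (is.na(wt_in_structure) ||
            !identical(aa_index(wt_in_structure), aa_index(mut$wt[i]))) {
          skipped <- skipped + 1L
          next
        }
        cache[[key]] <- predict_residue_profile(
          s, models, mut$chain[i], mut$position[i], sampling = sampling,
          voxel = voxel)$probabilities
      }
      p <- cache[[key]]
    }
    if (is.null(p)) { skipped <- skipped + 1L; next }
    scores[i] <- log_odds(p, mut$wt[i], mut$mut[i])
  }
  if (skipped > 0) message(skipped, " mutation(s) skipped (unresolvable or wild-type mismatch)")
  mut$log_odds <- scores
  corr_for <- function(col) {
    if (!col %in% names(mut)) return(NULL)
    ok <- !is.na(mut$log_odds) & !is.na(mut[[col]])
    n <- sum(ok)
    tibble::tibble(
      property = col,
      pearson = if (n >= 3) pearson_r(mut$log_odds[ok], mut[[col]][ok]) else NA_real_,
      spearman = if (n >= 3) spearman_rho(mut$log_odds[ok], mut[[col]][ok]) else NA_real_,
      n = n)
  }
  structure(list(scores = mut,
                 correlations = dplyr::bind_rows(corr_for("dTm"), corr_for("ddG")),
                 n_skipped = skipped),
            class = "zero_shot_benchmark")
}

# correlation coefficients written out from their defining formulas; the
# stats::cor implementations serve as an independent cross-check in tests
pearson_r <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

spearman_rho <- function(x, y) {
  pearson_r(rank(x), rank(y))
}

#' Rank candidate point mutations across a structure
#'
#' For every protein residue of a chain, predicts the masked-residue profile
#' and reports the best non-wild-type amino acid with its log-odds score,
#' sorted descending. Rows are annotated with the distance from the residue
#' to the nearest ligand atom and the interface kind; an optional
#' `max_ligand_distance` filter keeps only active-site-proximal positions.
#'
#' @param structure Annotated structure.
#' @param models A `resnet3d` or list of models.
#' @param chain Chain to scan (default first protein chain).
#' @param max_ligand_distance Optional distance filter in Angstrom.
#' @param top_k Optional row cap after sorting.
#' @param sampling,voxel Featurization configurations.
#' @return Tibble: `chain`, `residue_seq`, `wt_aa`, `best_mut`, `log_odds`,
#'   `ligand_distance`, `interface_kind`, sorted by descending `log_odds`.
#' @export
rank_designs <- function(structure, models, chain = NULL,
                         max_ligand_distance = NULL, top_k = NULL,
                         sampling = sampling_config(), voxel = voxel_config()) {
  res <- residue_table(structure)
  res <- res[res$entity_class == "protein", , drop = FALSE]
  if (is.null(chain)) chain <- res$chain[1]
  res <- res[res$chain == chain, , drop = FALSE]
  a <- structure$atoms
  lig <- a[a$entity_class == "ligand", , drop = FALSE]
  rows <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    prof <- predict_residue_profile(structure, models, chain,
                                    res$residue_seq[i], res$insert[i],
                                    sampling, voxel)
    wt_i <- prof$key$wt_aa
    if (is.na(wt_i)) next
    p <- prof$probabilities
    cand <- setdiff(seq_along(p), wt_i)
    best <- cand[which.max(p[cand])]
    ra <- a[a$chain == chain & a$residue_seq == res$residue_seq[i] &
              a$insert == res$insert[i], , drop = FALSE]
    ldist <- if (nrow(lig)) {
      sqrt(min(outer(ra$x, lig$x, "-")^2 + outer(ra$y, lig$y, "-")^2 +
                 outer(ra$z, lig$z, "-")^2))
    } else NA_real_
    rows[[i]] <- tibble::tibble(
      chain = chain, residue_seq = res$residue_seq[i],
      wt_aa = aa_alphabet()[wt_i], best_mut = aa_alphabet()[best],
      log_odds = log(p[[best]]) - log(p[[wt_i]]),
      ligand_distance = ldist,
      interface_kind = prof$interface_kind)
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$log_odds))
  if (!is.null(max_ligand_distance)) {
    out <- out[!is.na(out$ligand_distance) &
                 out$ligand_distance <= max_ligand_distance, , drop = FALSE]
  }
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}
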