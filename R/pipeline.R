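#' Fit, select and scale all models for one species pair
#'
#' End-to-end analysis of one pair's block table: builds the (optionally
#' normalised, optionally conditioned) S-distribution, fits the four
#' divergence models, runs hierarchical model selection, and converts the
#' best fit to natural units. Optionally writes the per-pair results,
#' selection and derived-estimates TSVs.
#'
#' @param blocks A block-record data frame, or a path to a block-table TSV.
#' @param pair_id Identifier used in outputs.
#' @param normalize_total Total S-distribution weight after the cross-pair
#'   normalisation (default 500); `NULL` fits the raw counts.
#' @param conditioned Exclude the monomorphic class (`S = 0`) and fit the
#'   conditioned likelihood.
#' @param mm [mutation_model()] used for natural-unit scaling.
#' @param bounds,n_starts,seed Passed to [fit_all_models()].
#' @param thresholds [select_thresholds()] for model selection.
#' @param out_dir If non-`NULL`, directory receiving `<pair_id>_fits.tsv`,
#'   `<pair_id>_selection.tsv` and `<pair_id>_derived.tsv`.
#' @return A list with elements `fits` (named list of `div_fit`),
#'   `selection` (one-row `div_selection` tibble) and `derived` (one-row
#'   tibble of natural-unit estimates for the best model).
#' @examples
#' blocks <- simulate_blocks(sim_config("SI", model_params(theta = 1, T0 = 1),
#'                                      n_blocks = 300, seed = 5))
#' res <- run_pair(blocks, pair_id = "demo", n_starts = 4)
#' res$selection
#' @export
run_pair <- function(blocks, pair_id = "pair", normalize_total = 500,
                     conditioned = FALSE, mm = mutation_model(),
                     bounds = default_bounds(), n_starts = 8, seed = 1,
                     thresholds = select_thresholds(), out_dir = NULL) {
  if (is.character(blocks) && length(blocks) == 1L) {
    blocks <- read_block_table(blocks)
  }
  sdist <- tryCatch(
    build_sdist(blocks, normalize_total = normalize_total, pair_id = pair_id),
    error = function(e) stop("pair ", pair_id, ": ", conditionMessage(e),
                             call. = FALSE))
  fits <- fit_all_models(sdist, bounds = bounds, n_starts = n_starts,
                         seed = seed, conditioned = conditioned)
  selection <- select_best(fits, thresholds = thresholds)
  best <- fits[[selection$best_model]]
  derived <- dplyr::bind_cols(tibble::tibble(pair_id = pair_id),
                              to_natural_units(best, mm))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(fits_table(fits, pair_id),
                     file.path(out_dir, paste0(pair_id, "_fits.tsv")))
    readr::write_tsv(selection_table(selection),
                     file.path(out_dir, paste0(pair_id, "_selection.tsv")))
    readr::write_tsv(derived, file.path(out_dir, paste0(pair_id, "_derived.tsv")))
  }
  list(fits = fits, selection = selection, derived = derived)
}

#' Per-pair fit table
#'
#' @param fits Named list of `div_fit` objects.
#' @param pair_id Identifier.
#' @return Tibble with one row per model: `pair_id`, `model`, the five
#'   parameters, `lnL`, `converged`, `at_boundary`, `conditioned`.
#' @export
fits_table <- function(fits, pair_id = "pair") {
  purrr::map_dfr(fits, function(ft) {
    p <- ft$params %||% model_params(NA_real_, 0)
    tibble::tibble(pair_id = pair_id, model = ft$model,
                   theta = p$theta, T0 = p$T0, T1 = p$T1, M = p$M, f = p$f,
                   lnL = ft$lnL, converged = ft$converged,
                   at_boundary = paste(ft$at_boundary, collapse = ","),
                   conditioned = ft$conditioned)
  })
}

selection_table <- function(selection) {
  tibble::tibble(
    pair_id = selection$pair_id, best_model = selection$best_model,
    `2dLL_SI_IM` = selection$two_delta_si_im,
    `2dLL_SI_SC` = selection$two_delta_si_sc,
    `2dLL_IM_SC` = selection$two_delta_im_sc,
    `2dLL_IM_IIM` = selection$two_delta_im_iim,
    nonidentifiable = selection$nonidentifiable
  )
}

#' Read a pair-metadata table
#'
#' Tab-separated with header `pair_id  geography  premating_RI
#' postzygotic_RI`; geography must be `sympatric` or `allopatric`, and the
#' reproductive-isolation indices, when present, must lie in `[0, 1]`
#' (missing values allowed).
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_pair_meta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                              stringsAsFactors = FALSE))
  need <- c("pair_id", "geography")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !meta$geography %in% c("sympatric", "allopatric")
  if (any(bad)) {
    stop("geography must be 'sympatric' or 'allopatric' (pair ",
         meta$pair_id[which(bad)[1]], ")", call. = FALSE)
  }
  for (col in intersect(c("premating_RI", "postzygotic_RI"), names(meta))) {
    x <- meta[[col]]
    if (any(!is.na(x) & (x < 0 | x > 1))) {
      stop(col, " must lie in [0, 1]", call. = FALSE)
    }
  }
  meta
}

#' Compare a fitted quantity between sympatric and allopatric pairs
#'
#' Joins per-pair results with pair metadata and contrasts the two
#' geography groups, either with a two-sample Wilcoxon rank-sum test on a
#' continuous variable or with a Fisher exact test on a 2x2 table of a
#' logical variable (e.g. best-model-is-SC) against geography.
#'
#' @param results A data frame with a `pair_id` column and the variable of
#'   interest — typically row-bound selection or derived-estimate tables.
#' @param meta Pair metadata from [read_pair_meta()] (columns `pair_id`,
#'   `geography`, optional RI indices; RI columns are joined into
#'   `results` automatically so they can be used as `variable`).
#' @param variable Column to contrast (continuous for Wilcoxon, logical for
#'   Fisher).
#' @param test `"wilcoxon"` or `"fisher"`.
#' @param alternative Test sidedness (passed to the underlying test;
#'   `"greater"` for a one-tailed Fisher test of enrichment in sympatric
#'   pairs).
#' @param exclude_nonidentifiable Drop pairs flagged non-identifiable
#'   (requires a `nonidentifiable` column in `results`).
#' @return A one-row tibble. For Wilcoxon: `statistic_W` (the Mann-Whitney
#'   U convention, rank-sum minus its minimum, as reported by
#'   [stats::wilcox.test()]), `statistic_ranksum` (sympatric-group rank
#'   sum), `p_value`, group sizes. For Fisher: the 2x2 counts, `odds_ratio`
#'   and `p_value`.
#' @export
compare_groups <- function(results, meta, variable,
                           test = c("wilcoxon", "fisher"),
                           alternative = "two.sided",
                           exclude_nonidentifiable = FALSE) {
  test <- match.arg(test)
  ri_cols <- intersect(c("premating_RI", "postzygotic_RI"), names(meta))
  dat <- dplyr::inner_join(results,
                           meta[c("pair_id", "geography", ri_cols)],
                           by = "pair_id",
                           suffix = c("", ".meta"))
  if (exclude_nonidentifiable) {
    if (!"nonidentifiable" %in% names(dat)) {
      stop("results lack a 'nonidentifiable' column", call. = FALSE)
    }
    dat <- dplyr::filter(dat, !.data$nonidentifiable)
  }
  if (!variable %in% names(dat)) {
    stop("variable '", variable, "' absent from results/metadata", call. = FALSE)
  }
  dat <- dplyr::filter(dat, !is.na(.data[[variable]]))
  sym <- dat[dat$geography == "sympatric", ][[variable]]
  allo <- dat[dat$geography == "allopatric", ][[variable]]
  if (length(sym) == 0 || length(allo) == 0) {
    stop("both geography groups must be non-empty", call. = FALSE)
  }
  if (test == "wilcoxon") {
    wt <- stats::wilcox.test(sym, allo, alternative = alternative, exact = NULL)
    n1 <- length(sym)
    ranksum <- sum(rank(c(sym, allo))[seq_len(n1)])
    tibble::tibble(test = "wilcoxon", variable = variable,
                   statistic_W = unname(wt$statistic),
                   statistic_ranksum = ranksum,
                   p_value = wt$p.value,
                   n_sympatric = n1, n_allopatric = length(allo),
                   alternative = alternative)
  } else {
    if (!is.logical(dat[[variable]])) {
      stop("fisher test needs a logical variable (e.g. best_model == 'SC')",
           call. = FALSE)
    }
    tab <- table(factor(dat$geography, c("sympatric", "allopatric")),
                 factor(dat[[variable]], c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab, alternative = alternative)
    tibble::tibble(test = "fisher", variable = variable,
                   sympatric_true = tab[1, 1], sympatric_false = tab[1, 2],
                   allopatric_true = tab[2, 1], allopatric_false = tab[2, 2],
                   odds_ratio = unname(ft$estimate), p_value = ft$p.value,
                   alternative = alternative)
  }
}

#' @importFrom rlang .data
NULL
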