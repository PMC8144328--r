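#' Read a per-SNP weight table
#'
#' Weight tables carry the published per-SNP instrument weights: one row
#' per SNP with the BMI-increasing (effect) allele and its per-allele
#' effect size. Expected TSV columns: `snp_id`, `effect_allele`, `weight`,
#' optionally `imputation_r2` and `score_name`.
#'
#' @param path TSV file path.
#' @param score_name Optional label overriding / filling the `score_name`
#'   column.
#' @return A tibble with at least `snp_id`, `effect_allele`, `weight`.
#' @export
read_weights <- function(path, score_name = NULL) {
  w <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("snp_id", "effect_allele", "weight")
  miss <- setdiff(need, names(w))
  if (length(miss)) {
    stop("weight table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(score_name)) w$score_name <- score_name
  validate_weights(w)
}

validate_weights <- function(weights) {
  if (anyDuplicated(weights$snp_id)) {
    stop("duplicated SNP ids in weight table: ",
         paste(unique(weights$snp_id[duplicated(weights$snp_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(weights$weight)) || any(weights$weight <= 0)) {
    stop("weights must be strictly positive once oriented to the ",
         "BMI-increasing allele", call. = FALSE)
  }
  tibble::as_tibble(weights)
}

#' Apply the SNP-exclusion cascade to a weight table
#'
#' Removes SNPs in three passes, mirroring the quality cascade applied to
#' published BMI scores before use as instruments:
#' 1. poor imputation quality (`imputation_r2 < r2_min`),
#' 2. membership in an explicit exclusion list (e.g. SNPs associated with
#'    smoking phenotypes, or SNPs flagged as pleiotropic),
#' 3. greedy linkage-disequilibrium pruning: SNP pairs with pairwise
#'    r-squared above `ld_max` are resolved by keeping the SNP with the
#'    larger absolute weight (ties broken lexicographically by SNP id).
#'
#' Every removal is logged with its reason in the `filter_log` attribute
#' of the result.
#'
#' @param weights Weight table (see [read_weights()]).
#' @param imputation_r2 Named numeric vector of per-SNP imputation
#'   quality, or `NULL` to skip the imputation filter. If supplied, every
#'   SNP in `weights` must be present in it (no silent pass-through); a
#'   column `imputation_r2` in `weights` is used when the argument is
#'   missing.
#' @param exclusion_list Character vector of SNP ids to drop.
#' @param ld_pairs Tibble/data frame with columns `snp1`, `snp2`, `r2`
#'   (treated as symmetric), or `NULL`. When `NULL` and `dosages` is
#'   given, pairwise r-squared is estimated from sample dosage
#'   correlations (flagged in the log).
#' @param dosages Optional genotype tibble (see [simulate_cohort()]) used
#'   to estimate LD when `ld_pairs` is absent.
#' @param r2_min Imputation-quality threshold in (0, 1]; default 0.3.
#' @param ld_max LD r-squared threshold in (0, 1]; default 0.2.
#' @return The filtered weight table, with attribute `filter_log`: a
#'   tibble of `snp_id`, `reason`.
#' @export
#' @examples
#' w <- tibble::tibble(snp_id = c("rs1", "rs2", "rs3"),
#'                     effect_allele = "A", weight = c(0.3, 0.2, 0.1))
#' ld <- tibble::tibble(snp1 = "rs1", snp2 = "rs2", r2 = 0.5)
#' filter_snps(w, ld_pairs = ld)
filter_snps <- function(weights, imputation_r2 = NULL,
                        exclusion_list = character(),
                        ld_pairs = NULL, dosages = NULL,
                        r2_min = 0.3, ld_max = 0.2) {
  weights <- validate_weights(weights)
  stopifnot(r2_min > 0, r2_min <= 1, ld_max > 0, ld_max <= 1)
  log <- tibble::tibble(snp_id = character(), reason = character())
  drop_snps <- function(w, ids, reason) {
    if (!length(ids)) return(w)
    log <<- dplyr::bind_rows(log, tibble::tibble(snp_id = ids, reason = reason))
    dplyr::filter(w, !.data$snp_id %in% ids)
  }

  if (is.null(imputation_r2) && "imputation_r2" %in% names(weights)) {
    imputation_r2 <- stats::setNames(weights$imputation_r2, weights$snp_id)
  }
  if (!is.null(imputation_r2)) {
    missing <- setdiff(weights$snp_id, names(imputation_r2))
    if (length(missing)) {
      stop("no imputation r2 available for SNP(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    bad <- weights$snp_id[imputation_r2[weights$snp_id] < r2_min]
    weights <- drop_snps(weights, bad,
                         sprintf("imputation_r2 < %g", r2_min))
  }

  weights <- drop_snps(weights,
                       intersect(weights$snp_id, exclusion_list),
                       "exclusion list")

  if (is.null(ld_pairs) && !is.null(dosages)) {
    present <- intersect(weights$snp_id, names(dosages))
    if (length(present) >= 2) {
      cm <- stats::cor(as.matrix(dosages[present]))^2
      idx <- which(upper.tri(cm), arr.ind = TRUE)
      ld_pairs <- tibble::tibble(snp1 = present[idx[, 1]],
                                 snp2 = present[idx[, 2]],
                                 r2 = cm[idx])
      log <- dplyr::bind_rows(
        log, tibble::tibble(snp_id = NA_character_,
                            reason = "LD estimated from sample dosage correlations"))
    }
  }
  if (!is.null(ld_pairs)) {
    lp <- dplyr::filter(tibble::as_tibble(ld_pairs), .data$r2 > ld_max)
    if (nrow(lp)) {
      # greedy prune: visit SNPs by decreasing |weight| (ties: snp id),
      # keep a SNP unless a previously kept SNP partners it above ld_max
      ord <- weights[order(-abs(weights$weight), weights$snp_id), ]
      partners <- rbind(as.matrix(lp[, c("snp1", "snp2")]),
                        as.matrix(lp[, c("snp2", "snp1")]))
      kept <- character()
      pruned <- character()
      for (s in ord$snp_id) {
        linked <- partners[partners[, 1] == s, 2]
        if (any(linked %in% kept)) pruned <- c(pruned, s) else kept <- c(kept, s)
      }
      weights <- drop_snps(weights, pruned,
                           sprintf("LD r2 > %g with retained higher-weight SNP", ld_max))
    }
  }

  attr(weights, "filter_log") <- log
  weights
}

#' Compute a weighted allele score
#'
#' The score of individual i is the weighted sum over retained SNPs of
#' the dosage of the BMI-increasing allele,
#' `score_i = sum_j w_j d_ij`. The raw weighted sum is the default scale
#' (matching earlier MR studies of BMI); `rescale = TRUE` divides by the
#' sum of the weights, putting the score on a per-BMI-increasing-allele
#' scale.
#'
#' @param genotypes Tibble with `id` and one dosage column per SNP
#'   (dosages in \[0, 2\], fractional allowed).
#' @param weights Weight table (see [read_weights()], [filter_snps()]).
#' @param missing_policy `"error"`: any `NA` dosage among required SNPs is
#'   an error. `"mean_impute"`: `NA` dosages are replaced by twice the
#'   effect-allele frequency estimated from the sample (mean dosage / 2).
#'   A SNP absent from the genotype matrix altogether is always an error.
#' @param allele_info Optional tibble `snp_id`, `effect_allele` giving the
#'   orientation of the dosage columns; mismatches with the weight table
#'   are an error listing the offending SNPs. No strand flipping is
#'   attempted.
#' @param rescale Divide by `sum(weights)` (per-allele scale)?
#' @return A tibble `id`, `score`, `score_name`, `n_snps_used`.
#' @export
#' @examples
#' g <- tibble::tibble(id = c("a", "b"), rs1 = c(2, 0), rs2 = c(1, 0))
#' w <- tibble::tibble(snp_id = c("rs1", "rs2"), effect_allele = "A",
#'                     weight = c(0.1, 0.2))
#' compute_score(g, w)
compute_score <- function(genotypes, weights,
                          missing_policy = c("error", "mean_impute"),
                          allele_info = NULL, rescale = FALSE) {
  missing_policy <- match.arg(missing_policy)
  weights <- validate_weights(weights)
  absent <- setdiff(weights$snp_id, names(genotypes))
  if (length(absent)) {
    stop("weight-table SNP(s) absent from genotype matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!is.null(allele_info)) {
    ori <- dplyr::inner_join(weights[c("snp_id", "effect_allele")],
                             tibble::as_tibble(allele_info),
                             by = "snp_id", suffix = c("", ".geno"))
    bad <- ori$snp_id[ori$effect_allele != ori$effect_allele.geno]
    if (length(bad)) {
      stop("effect-allele mismatch with genotype orientation for SNP(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  D <- as.matrix(genotypes[weights$snp_id])
  if (any(D < 0 | D > 2, na.rm = TRUE)) {
    stop("dosages outside [0, 2]", call. = FALSE)
  }
  if (anyNA(D)) {
    if (missing_policy == "error") {
      stop("missing dosages for ",
           paste(weights$snp_id[colSums(is.na(D)) > 0], collapse = ", "),
           "; use missing_policy = \"mean_impute\" to fill them",
           call. = FALSE)
    }
    fill <- colMeans(D, na.rm = TRUE)    # = 2 * sample allele frequency
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- fill[idx[, 2]]
  }
  w <- weights$weight
  score <- drop(D %*% w)
  if (rescale) score <- score / sum(w)
  tibble::tibble(
    id = genotypes$id,
    score = score,
    score_name = if ("score_name" %in% names(weights))
      weights$score_name[1] else "custom",
    n_snps_used = nrow(weights)
  )
}

#' Pairwise correlation of allele scores
#'
#' @param scores A list of score tibbles from [compute_score()] (or a
#'   single wide tibble with an `id` column and one column per score).
#'   All scores must cover an identical set of individuals.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
score_correlation <- function(scores) {
  if (is.data.frame(scores)) {
    wide <- tibble::as_tibble(scores)
  } else {
    stopifnot(length(scores) >= 2)
    nm <- purrr::imap_chr(scores, function(s, i) {
      if ("score_name" %in% names(s)) as.character(s$score_name[1])
      else paste0("score", i)
    })
    nm <- make.unique(nm)
    ids <- scores[[1]]$id
    for (s in scores[-1]) {
      if (!setequal(s$id, ids)) {
        stop("scores cover different individual id sets", call. = FALSE)
      }
    }
    cols <- purrr::map2(scores, nm, function(s, n) {
      stats::setNames(tibble::tibble(s$score[match(ids, s$id)]), n)
    })
    wide <- dplyr::bind_cols(tibble::tibble(id = ids), cols)
  }
  m <- stats::cor(as.matrix(dplyr::select(wide, -dplyr::any_of("id"))))
  diag(m) <- 1
  m
}
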