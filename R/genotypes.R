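#' Genotype matrix for a biparental mapping population
#'
#' Markers are grouped by scaffold and sorted by position; calls are
#' parental-allele tokens: `A` (reference parent), `B` (alternative
#' parent), `-` (missing, including heterozygous calls collapsed to
#' missing in an inbred population).
#'
#' @param markers data frame with `marker_id`, `scaffold_id`,
#'   `position` (0-based) and optionally `type` (`SNP`/`SSR`).
#' @param calls character matrix, rows = markers (in `markers` order),
#'   columns = individuals, entries in `A`, `B`, `-`.
#' @param individuals individual ids; defaults to `colnames(calls)`.
#' @return an object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(markers, calls, individuals = colnames(calls)) {
  if (is.null(markers$type)) markers$type <- "SNP"
  stopifnot(is.matrix(calls), nrow(calls) == nrow(markers))
  if (anyDuplicated(individuals))
    stop("individual ids must be unique", call. = FALSE)
  if (anyDuplicated(markers$marker_id))
    stop("duplicated marker_id: ",
         markers$marker_id[duplicated(markers$marker_id)][1],
         call. = FALSE)
  ord <- order(markers$scaffold_id, markers$position)
  markers <- markers[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  rownames(markers) <- NULL
  for (sc in unique(markers$scaffold_id)) {
    p <- markers$position[markers$scaffold_id == sc]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on ", sc, call. = FALSE)
  }
  if (!all(calls %in% c("A", "B", "-")))
    stop("calls must be A, B or -", call. = FALSE)
  rownames(calls) <- markers$marker_id
  colnames(calls) <- individuals
  structure(list(markers = markers, calls = calls,
                 individuals = individuals),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d markers x %d individuals on %d scaffold(s)\n",
              nrow(x$markers), length(x$individuals),
              length(unique(x$markers$scaffold_id))))
  invisible(x)
}

#' Call genotypes from allele depths
#'
#' An individual is called `A` when only the reference allele is
#' observed with at least `depth_min` reads, `B` when only the
#' alternative allele is observed with at least `depth_min` reads, and
#' missing (`-`) when both alleles are observed (heterozygous, not
#' expected in an inbred line) or the supporting depth is below the
#' threshold.
#'
#' @param ref_depth,alt_depth integer matrices (markers x individuals)
#'   of reads supporting each allele.
#' @param markers marker data frame (see [genotype_matrix()]).
#' @param config a [pipeline_config()].
#' @return a `GenotypeMatrix`.
#' @export
call_genotypes <- function(ref_depth, alt_depth, markers, config = NULL) {
  config <- as_config(config)
  if (any(ref_depth < 0) || any(alt_depth < 0))
    stop("negative read depths", call. = FALSE)
  calls <- matrix("-", nrow(ref_depth), ncol(ref_depth))
  calls[ref_depth >= config$depth_min & alt_depth == 0] <- "A"
  calls[alt_depth >= config$depth_min & ref_depth == 0] <- "B"
  colnames(calls) <- colnames(ref_depth)
  genotype_matrix(markers, calls)
}

#' Filter markers on minor-allele frequency and missingness
#'
#' A marker is kept iff its minor-allele frequency among non-missing
#' calls is at least `maf_min` and its fraction of missing calls over
#' all individuals is at most `missing_max`. The rejection report lists
#' each discarded marker with a reason (`monomorphic/MAF`, `missing`,
#' `all-missing`).
#'
#' @param gm a `GenotypeMatrix`.
#' @param config a [pipeline_config()].
#' @return list with `kept` (`GenotypeMatrix`) and `rejected` (data
#'   frame `marker_id`, `reason`, `maf`, `missing_frac`).
#' @export
filter_markers <- function(gm, config = NULL) {
  config <- as_config(config)
  n_ind <- length(gm$individuals)
  nA <- rowSums(gm$calls == "A")
  nB <- rowSums(gm$calls == "B")
  n_called <- nA + nB
  missing_frac <- 1 - n_called / n_ind
  maf <- ifelse(n_called > 0, pmin(nA, nB) / n_called, NA_real_)
  reason <- rep(NA_character_, nrow(gm$markers))
  reason[n_called == 0] <- "all-missing"
  reason[is.na(reason) & missing_frac > config$missing_max] <- "missing"
  reason[is.na(reason) & maf < config$maf_min] <- "monomorphic/MAF"
  keep <- is.na(reason)
  kept <- genotype_matrix(gm$markers[keep, , drop = FALSE],
                          gm$calls[keep, , drop = FALSE],
                          gm$individuals)
  rejected <- data.frame(marker_id = gm$markers$marker_id[!keep],
                         reason = reason[!keep],
                         maf = maf[!keep],
                         missing_frac = missing_frac[!keep],
                         stringsAsFactors = FALSE)
  list(kept = kept, rejected = rejected)
}

#' Integrate SNP and SSR marker sets into one map
#'
#' Forms the union of the two marker sets on the same individuals,
#' re-sorted by scaffold and position, and reports the marker
#' bookkeeping (n_snp + n_ssr = n_total).
#'
#' @param snp_gm `GenotypeMatrix` of SNP markers.
#' @param ssr_gm `GenotypeMatrix` of SSR markers (same individuals).
#' @return list with `integrated` (`GenotypeMatrix`) and `summary`
#'   (`n_snp`, `n_ssr`, `n_total`).
#' @export
integrate_maps <- function(snp_gm, ssr_gm) {
  if (!identical(snp_gm$individuals, ssr_gm$individuals))
    stop("marker sets genotyped on different individuals", call. = FALSE)
  dup <- intersect(snp_gm$markers$marker_id, ssr_gm$markers$marker_id)
  if (length(dup))
    stop("marker_id present in both sets: ", dup[[1]], call. = FALSE)
  snp_gm$markers$type <- rep("SNP", nrow(snp_gm$markers))
  ssr_gm$markers$type <- rep("SSR", nrow(ssr_gm$markers))
  markers <- rbind(snp_gm$markers, ssr_gm$markers)
  calls <- rbind(snp_gm$calls, ssr_gm$calls)
  integrated <- genotype_matrix(markers, calls, snp_gm$individuals)
  list(integrated = integrated,
       summary = list(n_snp = nrow(snp_gm$markers),
                      n_ssr = nrow(ssr_gm$markers),
                      n_total = nrow(integrated$markers)))
}

#' Pairwise linkage disequilibrium (r-squared) between markers
#'
#' r2 is computed from haplotype frequencies over individuals with
#' non-missing calls at both markers:
#' `r2 = (pAB - pA pB)^2 / (pA (1-pA) pB (1-pB))`.
#' Pairs with fewer than two complete individuals, or where either
#' marker is monomorphic among complete individuals, are reported as
#' `NA` with a flag.
#'
#' @param gm a `GenotypeMatrix`.
#' @param pairs two-column matrix or data frame of marker ids; if
#'   `NULL`, all pairs within `window` consecutive markers per scaffold.
#' @param window marker window for all-vs-all mode.
#' @return data frame `marker1`, `marker2`, `n_complete`, `r2`, `flag`.
#' @export
ld_r2 <- function(gm, pairs = NULL, window = 10L) {
  if (is.null(pairs)) {
    idx <- list()
    for (sc in unique(gm$markers$scaffold_id)) {
      rows <- which(gm$markers$scaffold_id == sc)
      for (i in seq_along(rows)) {
        if (i >= length(rows)) next
        j <- rows[seq(i + 1L, min(i + window, length(rows)))]
        if (length(j))
          idx[[length(idx) + 1L]] <-
            cbind(gm$markers$marker_id[rows[[i]]],
                  gm$markers$marker_id[j])
      }
    }
    pairs <- do.call(rbind, idx)
  }
  pairs <- as.matrix(pairs)
  out <- data.frame(marker1 = pairs[, 1], marker2 = pairs[, 2],
                    n_complete = NA_integer_, r2 = NA_real_,
                    flag = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    a <- gm$calls[pairs[k, 1], ]
    b <- gm$calls[pairs[k, 2], ]
    ok <- a != "-" & b != "-"
    out$n_complete[[k]] <- sum(ok)
    if (sum(ok) < 2) { out$flag[[k]] <- "too-few-complete"; next }
    x <- as.integer(a[ok] == "B")
    y <- as.integer(b[ok] == "B")
    pa <- mean(x); pb <- mean(y)
    if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
      out$flag[[k]] <- "monomorphic"; next
    }
    pab <- mean(x == 1 & y == 1)
    out$r2[[k]] <- (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
  }
  out
}
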