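#' Parse and render Medtr-style gene identifiers
#'
#' Identifiers have the form `Medtr<chrom>g<6 digits>`, e.g.
#' `Medtr1g009000`: a chromosome token (1-8, or a scaffold token for
#' unplaced genes) and a six-digit number whose order tracks the
#' gene's position along the chromosome.
#'
#' @param id character vector of identifiers.
#' @return data frame with `id`, `chrom`, `numeric` (integer value of
#'   the six digits) and `series` (first digit). Non-conforming ids
#'   (e.g. `contig999_1` legacy contig genes) get `NA` fields.
#' @export
parse_gene_id <- function(id) {
  m <- regmatches(id, regexec("^Medtr([0-9]+|[A-Za-z0-9]+?)g([0-9]{6})$",
                              id))
  chrom <- vapply(m, function(x) if (length(x)) x[[2]] else NA_character_,
                  character(1))
  num <- vapply(m, function(x) if (length(x)) x[[3]] else NA_character_,
                character(1))
  data.frame(id = id, chrom = chrom, numeric = as.integer(num),
             series = as.integer(substr(num, 1, 1)),
             stringsAsFactors = FALSE)
}

#' @rdname parse_gene_id
#' @param chrom chromosome token.
#' @param numeric integer in 0..999999.
#' @export
format_gene_id <- function(chrom, numeric) {
  stopifnot(all(numeric >= 0 & numeric <= 999999))
  sprintf("Medtr%sg%06d", chrom, as.integer(numeric))
}

#' Identifier registry
#'
#' Tracks every identifier ever issued in the old or new release so
#' that minted identifiers are globally unique and retired
#' identifiers are never re-used.
#'
#' @param ids character vector of identifiers to pre-register.
#' @return an environment-backed registry.
#' @export
id_registry <- function(ids = character(0)) {
  reg <- new.env(parent = emptyenv())
  reg$used <- new.env(parent = emptyenv())
  registry_add(reg, ids)
  class(reg) <- "id_registry"
  reg
}

#' @rdname id_registry
#' @param registry an `id_registry`.
#' @export
registry_add <- function(registry, ids) {
  for (id in ids) {
    if (!is.na(id)) assign(id, TRUE, envir = registry$used)
  }
  invisible(registry)
}

#' @rdname id_registry
#' @export
registry_has <- function(registry, ids) {
  vapply(ids, function(id) exists(id, envir = registry$used),
         logical(1), USE.NAMES = FALSE)
}

#' Mint new gene identifiers between two existing ones
#'
#' Inserts `n_new` identifiers into the reserved numeric range between
#' two flanking gene identifiers on the same chromosome. The stride is
#' the largest of `id_strides` (default 10, 5, 3, 2) such that
#' `n_new * stride` still fits strictly inside the range, so that room
#' remains for future genes. When no stride fits, the overflow series
#' is used: a `4` is inserted as the first digit, and identifiers run
#' `400000 + left + 10 k`, skipping any identifier already present in
#' the registry. Either way the minted identifiers preserve the
#' chromosomal ordering information the scheme encodes.
#'
#' @param left_id,right_id flanking identifiers (same chromosome,
#'   `left < right` numerically).
#' @param n_new number of identifiers to mint.
#' @param registry optional [id_registry()]; minted ids are recorded
#'   in it and colliding overflow ids are skipped.
#' @param config a [pipeline_config()] (supplies `id_strides`).
#' @return list with `ids` (character), `numerics`, `stride` (the
#'   stride used, `NA` in overflow mode) and `overflow` (logical).
#' @export
#' @examples
#' assign_new_ids("Medtr1g009000", "Medtr1g009050", 2)$ids
assign_new_ids <- function(left_id, right_id, n_new, registry = NULL,
                           config = NULL) {
  config <- as_config(config)
  l <- parse_gene_id(left_id); r <- parse_gene_id(right_id)
  if (is.na(l$numeric) || is.na(r$numeric))
    stop("flanking ids must be Medtr identifiers", call. = FALSE)
  if (l$chrom != r$chrom)
    stop("flanking ids lie on different chromosomes", call. = FALSE)
  if (l$numeric >= r$numeric)
    stop("left id must be numerically below right id", call. = FALSE)
  if (n_new < 0) stop("n_new must be >= 0", call. = FALSE)
  if (n_new == 0)
    return(list(ids = character(0), numerics = integer(0),
                stride = NA_integer_, overflow = FALSE))
  range <- r$numeric - l$numeric
  fits <- config$id_strides[n_new * config$id_strides < range]
  if (length(fits)) {
    stride <- fits[[1]]
    nums <- l$numeric + stride * seq_len(n_new)
    ids <- format_gene_id(l$chrom, nums)
    if (!is.null(registry)) {
      clash <- ids[registry_has(registry, ids)]
      if (length(clash))
        stop("identifier already issued: ", clash[[1]], call. = FALSE)
      registry_add(registry, ids)
    }
    return(list(ids = ids, numerics = nums, stride = stride,
                overflow = FALSE))
  }
  ## overflow series: insert '4' as the first digit
  base <- 400000L + l$numeric
  nums <- integer(0)
  k <- 1L
  while (length(nums) < n_new) {
    cand <- base + 10L * k
    k <- k + 1L
    if (cand > 999999L)
      stop("overflow series exhausted: ", n_new - length(nums),
           " identifier(s) cannot be placed after ",
           format_gene_id(l$chrom, base), call. = FALSE)
    if (!is.null(registry) &&
        registry_has(registry, format_gene_id(l$chrom, cand)))
      next
    nums <- c(nums, cand)
  }
  ids <- format_gene_id(l$chrom, nums)
  if (!is.null(registry)) registry_add(registry, ids)
  list(ids = ids, numerics = nums, stride = NA_integer_, overflow = TRUE)
}

#' Choose the legacy identifier to carry over for a merged locus
#'
#' When several legacy loci merge into one new locus, the retained
#' identifier is the one whose protein globally aligns best to the
#' new protein: candidates are ranked lexicographically by (identity,
#' coverage), where identity is matching columns over alignment
#' columns of a Needleman-Wunsch global alignment and coverage is
#' matching columns over the new protein length. Ties break toward
#' the older (numerically smaller) identifier. Candidates without a
#' protein sequence are excluded with a warning.
#'
#' @param new_protein amino-acid string of the new locus.
#' @param old_proteins named character vector (names = candidate
#'   legacy ids).
#' @return list with `chosen` (id), and `scores` data frame.
#' @export
resolve_merge_conflict <- function(new_protein, old_proteins) {
  keep <- !is.na(old_proteins) & nzchar(old_proteins)
  if (any(!keep))
    warning("candidate(s) without protein sequence excluded: ",
            paste(names(old_proteins)[!keep], collapse = ", "))
  old_proteins <- old_proteins[keep]
  if (!length(old_proteins))
    stop("no candidate with a protein sequence", call. = FALSE)
  scores <- lapply(names(old_proteins), function(id) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(old_proteins[[id]]),
      Biostrings::AAString(new_protein), type = "global")
    nm <- Biostrings::nmatch(pa)
    data.frame(old_id = id,
               identity = nm / Biostrings::nchar(pa),
               coverage = nm / nchar(new_protein),
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, scores)
  num <- parse_gene_id(scores$old_id)$numeric
  num[is.na(num)] <- .Machine$integer.max
  ord <- order(-scores$identity, -scores$coverage, num)
  scores <- scores[ord, ]
  rownames(scores) <- NULL
  list(chosen = scores$old_id[[1]], scores = scores)
}

#' Classify locus structure changes between two releases
#'
#' Lifts old loci onto the new assembly through a liftOver chain,
#' builds the same-strand overlap graph between lifted old loci and
#' new loci, and classifies each connected component: 1:1 with
#' identical CDS structure is `unchanged`, 1:1 otherwise `minor`,
#' k:1 `merge`, 1:k `split`; old loci that cannot be lifted are
#' `moved`, lifted loci without a counterpart `retired`, and new loci
#' without one `novel`.
#'
#' @param old_loci,new_loci data frames with `locus_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand` and optionally
#'   `cds` (comma-separated `start-end` pairs in locus coordinates on
#'   the genome, e.g. `"10-100,150-300"`).
#' @param chains chain list from [read_chain()] mapping old
#'   coordinates to new ones (identity chains for same-assembly
#'   comparison).
#' @return data frame `old_id`, `new_locus`, `relation`.
#' @export
classify_structure_changes <- function(old_loci, new_loci, chains) {
  lift_start <- lift_positions(chains, old_loci$chrom, old_loci$start)
  lift_end <- lift_positions(chains, old_loci$chrom, old_loci$end - 1L)
  old <- old_loci
  old$l_chrom <- lift_start$new_id
  old$l_start <- pmin(lift_start$new_pos, lift_end$new_pos)
  old$l_end <- pmax(lift_start$new_pos, lift_end$new_pos) + 1L
  flip <- !is.na(lift_start$strand) & lift_start$strand == "-"
  old$l_strand <- ifelse(flip,
                         ifelse(old$strand == "+", "-", "+"),
                         old$strand)
  liftable <- !is.na(old$l_chrom) & !is.na(lift_end$new_id) &
    old$l_chrom == lift_end$new_id
  rel <- list()
  ## overlap pairs on the new assembly
  edges <- list()
  for (i in which(liftable)) {
    hit <- which(new_loci$chrom == old$l_chrom[[i]] &
                   new_loci$strand == old$l_strand[[i]] &
                   new_loci$start < old$l_end[[i]] &
                   new_loci$end > old$l_start[[i]])
    for (j in hit) edges[[length(edges) + 1L]] <- c(i, j)
  }
  matched_old <- unique(vapply(edges, `[[`, integer(1), 1L))
  matched_new <- unique(vapply(edges, `[[`, integer(1), 2L))
  ## connected components (union-find over old+new nodes)
  n_old <- nrow(old); n_new <- nrow(new_loci)
  parent <- seq_len(n_old + n_new)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (e in edges) {
    a <- find(e[[1]]); b <- find(n_old + e[[2]])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n_old + n_new), find, integer(1))
  for (cid in unique(comp[c(matched_old, n_old + matched_new)])) {
    olds <- which(comp[seq_len(n_old)] == cid)
    olds <- intersect(olds, matched_old)
    news <- which(comp[n_old + seq_len(n_new)] == cid)
    news <- intersect(news, matched_new)
    relation <- if (length(olds) == 1 && length(news) == 1) {
      if (same_cds_structure(old[olds, ], new_loci[news, ], chains))
        "unchanged" else "minor"
    } else if (length(news) == 1) "merge"
    else if (length(olds) == 1) "split"
    else "merge" # complex k:m; dominant relation recorded
    for (i in olds) for (j in news)
      rel[[length(rel) + 1L]] <-
        data.frame(old_id = old$locus_id[[i]],
                   new_locus = new_loci$locus_id[[j]],
                   relation = relation, stringsAsFactors = FALSE)
  }
  for (i in setdiff(which(!liftable), matched_old))
    rel[[length(rel) + 1L]] <-
      data.frame(old_id = old$locus_id[[i]], new_locus = NA,
                 relation = "moved", stringsAsFactors = FALSE)
  for (i in setdiff(which(liftable), matched_old))
    rel[[length(rel) + 1L]] <-
      data.frame(old_id = old$locus_id[[i]], new_locus = NA,
                 relation = "retired", stringsAsFactors = FALSE)
  for (j in setdiff(seq_len(n_new), matched_new))
    rel[[length(rel) + 1L]] <-
      data.frame(old_id = NA, new_locus = new_loci$locus_id[[j]],
                 relation = "novel", stringsAsFactors = FALSE)
  out <- do.call(rbind, rel)
  rownames(out) <- NULL
  out
}

parse_cds_chain <- function(cds) {
  if (is.null(cds) || is.na(cds) || !nzchar(cds)) return(NULL)
  parts <- strsplit(strsplit(cds, ",")[[1]], "-")
  t(vapply(parts, as.integer, integer(2)))
}

same_cds_structure <- function(old_row, new_row, chains) {
  oc <- parse_cds_chain(old_row$cds)
  nc <- parse_cds_chain(new_row$cds)
  if (is.null(oc) || is.null(nc)) {
    ## no CDS detail: compare lifted span exactly
    return(old_row$l_start == new_row$start &&
             old_row$l_end == new_row$end)
  }
  if (nrow(oc) != nrow(nc)) return(FALSE)
  ## lift every CDS boundary and compare the sorted boundary sets
  bounds <- c(oc[, 1], oc[, 2] - 1L)
  lifted <- lift_positions(chains, rep(old_row$chrom, length(bounds)),
                           bounds)
  if (any(is.na(lifted$new_pos))) return(FALSE)
  want <- sort(c(nc[, 1], nc[, 2] - 1L))
  identical(sort(lifted$new_pos), as.integer(want))
}

#' Carry legacy identifiers over to new loci
#'
#' Applies the retention rules: a legacy `Medtr` identifier is kept by
#' the new locus it corresponds to (whole or in part); legacy
#' contig-style identifiers are never retained and the loci are
#' flagged for new identifiers; a retired identifier is never reused;
#' no identifier goes to two loci. When several legacy ids compete for
#' one new locus (merge) or one id is wanted by several new loci
#' (split), the pair with the highest `score` wins (compute scores
#' with [resolve_merge_conflict()]); ties break toward the smaller
#' numeric id.
#'
#' @param correspondences data frame `old_id`, `new_locus`,
#'   `relation` (from [classify_structure_changes()]), optionally
#'   `score`.
#' @param registry optional [id_registry()] recording all assigned
#'   ids.
#' @return data frame `new_locus`, `assigned_id` (`NA` = mint a new
#'   one), `status` (`carried` / `new-needed`).
#' @export
carry_over_ids <- function(correspondences, registry = NULL) {
  cc <- correspondences[!is.na(correspondences$new_locus), ,
                        drop = FALSE]
  new_loci <- unique(cc$new_locus)
  cand <- cc[!is.na(cc$old_id), , drop = FALSE]
  pg <- parse_gene_id(cand$old_id)
  cand <- cand[!is.na(pg$numeric), , drop = FALSE] # contig ids never retained
  num <- parse_gene_id(cand$old_id)$numeric
  if (is.null(cand$score)) cand$score <- 0
  cand <- cand[order(-cand$score, num), , drop = FALSE]
  assigned <- character(0) # new_locus -> id
  used <- character(0)
  for (k in seq_len(nrow(cand))) {
    nl <- cand$new_locus[[k]]; oid <- cand$old_id[[k]]
    if (nl %in% names(assigned) || oid %in% used) next
    if (!is.null(registry) && registry_has(registry, oid) &&
        !oid %in% cand$old_id) next
    assigned[[nl]] <- oid
    used <- c(used, oid)
  }
  out <- data.frame(new_locus = new_loci,
                    assigned_id = unname(assigned[new_loci]),
                    stringsAsFactors = FALSE)
  out$status <- ifelse(is.na(out$assigned_id), "new-needed", "carried")
  if (!is.null(registry)) registry_add(registry, out$assigned_id)
  out
}
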