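#' Schema-validated TSV readers for the pipeline's tabular inputs
#'
#' All tabular evidence enters the pipeline through one reader that
#' checks the header against a declared schema, coerces column types
#' and reports parse problems with line numbers.
#'
#' Available schemas:
#' \describe{
#'   \item{placements}{`scaffold_id, scaffold_start, scaffold_end,
#'     chrom_id, chrom_start, chrom_end, orientation` — a scaffold
#'     interval placed on a chromosome coordinate system (the
#'     map-placement abstraction of optical-map alignments).}
#'   \item{clone_links}{`end1_scaffold, end1_pos, end2_scaffold,
#'     end2_pos, library_mean, library_sd` — paired clone-end
#'     mappings with the library insert-size model.}
#'   \item{markers}{`marker_id, scaffold_id, position, type`.}
#'   \item{genotypes}{`marker_id` followed by one column per
#'     individual; cells in `A`, `B`, `-`.}
#'   \item{anchor_hits}{`gene_a, chrom_a, rank_a, gene_b, chrom_b,
#'     rank_b, score, ks` (`ks` may be `NA`).}
#' }
#'
#' @param path TSV file path (header row required).
#' @param schema one of `"placements"`, `"clone_links"`, `"markers"`,
#'   `"genotypes"`, `"anchor_hits"`.
#' @return a typed data frame; for `genotypes`, a list with `markers`
#'   (ids) and `calls` (character matrix markers x individuals).
#' @export
read_tsv_tables <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  schemas <- list(
    placements = c(scaffold_id = "character", scaffold_start = "integer",
                   scaffold_end = "integer", chrom_id = "character",
                   chrom_start = "integer", chrom_end = "integer",
                   orientation = "character"),
    clone_links = c(end1_scaffold = "character", end1_pos = "integer",
                    end2_scaffold = "character", end2_pos = "integer",
                    library_mean = "numeric", library_sd = "numeric"),
    markers = c(marker_id = "character", scaffold_id = "character",
                position = "integer", type = "character"),
    anchor_hits = c(gene_a = "character", chrom_a = "character",
                    rank_a = "integer", gene_b = "character",
                    chrom_b = "character", rank_b = "integer",
                    score = "numeric", ks = "numeric")
  )
  if (identical(schema, "genotypes")) return(read_genotype_tsv(path))
  sc <- schemas[[schema]]
  if (is.null(sc)) stop("unknown schema: ", schema, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE)
  miss <- setdiff(names(sc), names(df))
  if (length(miss))
    stop("missing column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[names(sc)]
  for (col in names(sc)) {
    if (sc[[col]] == "character") next
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(raw %in% c("NA", "", ".")))
    if (length(bad))
      stop(sprintf("%s line %d: cannot parse '%s' in column %s",
                   basename(path), bad[[1]] + 1L, raw[[bad[[1]]]], col),
           call. = FALSE)
    df[[col]] <- if (sc[[col]] == "integer") as.integer(val) else val
  }
  df$.line <- seq_len(nrow(df)) + 1L
  if (identical(schema, "placements") && nrow(df)) {
    if (!all(df$orientation %in% c("+", "-")))
      stop("placement orientation must be + or - (line ",
           df$.line[which(!df$orientation %in% c("+", "-"))[1]], ")",
           call. = FALSE)
    if (any(df$scaffold_end <= df$scaffold_start) ||
        any(df$chrom_end <= df$chrom_start))
      stop("placement intervals must be non-empty", call. = FALSE)
  }
  df
}

read_genotype_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE)
  if (names(df)[[1]] != "marker_id")
    stop("genotype table must start with a marker_id column",
         call. = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df$marker_id
  ok <- matrix(calls %in% c("A", "B", "-"), nrow = nrow(calls))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("genotype line %d: invalid token '%s'",
                 bad[1, 1] + 1L, calls[bad[1, 1], bad[1, 2]]),
         call. = FALSE)
  list(markers = df$marker_id, calls = calls,
       individuals = colnames(calls))
}

#' Write a genotype matrix as TSV (tokens A / B / -)
#' @param gm a `GenotypeMatrix` (see [genotype_matrix()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- data.frame(marker_id = gm$markers$marker_id,
                   gm$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
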