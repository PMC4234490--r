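#' AGP rows describing how components tile an object
#'
#' Construct a validated AGP row table (AGP v2.0 dialect). Component
#' rows (`W`) carry `component_id`, `component_beg/end` and
#' `orientation`; gap rows (`N` known length, `U` unknown length) carry
#' `gap_length`. Object coordinates are 1-based inclusive, as in the
#' format itself; package-internal 0-based coordinates are converted at
#' this boundary.
#'
#' @param df data frame with columns `object_id`, `object_beg`,
#'   `object_end`, `part_number`, `component_type` plus, for W rows,
#'   `component_id`, `component_beg`, `component_end`, `orientation`
#'   and, for N/U rows, `gap_length`.
#' @return the validated data frame with class `agp`.
#' @export
agp_rows <- function(df) {
  need <- c("object_id", "object_beg", "object_end", "part_number",
            "component_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("AGP table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("component_id", "component_beg", "component_end",
                "orientation", "gap_length")) {
    if (is.null(df[[col]])) df[[col]] <- NA
  }
  if (!all(df$component_type %in% c("W", "N", "U")))
    stop("component_type must be one of W, N, U", call. = FALSE)
  if (any(df$object_end < df$object_beg))
    stop("object_end < object_beg", call. = FALSE)
  for (obj in unique(df$object_id)) {
    rows <- df[df$object_id == obj, ]
    rows <- rows[order(rows$part_number), ]
    if (!identical(as.integer(rows$part_number),
                   seq_len(nrow(rows))))
      stop("part_number not 1..k for object ", obj, call. = FALSE)
    if (nrow(rows) > 1) {
      if (any(rows$object_beg[-1] != rows$object_end[-nrow(rows)] + 1L))
        stop("object intervals for ", obj,
             " are not contiguous and non-overlapping", call. = FALSE)
    }
    if (rows$object_beg[[1]] != 1L)
      stop("object ", obj, " does not start at 1", call. = FALSE)
    gaps <- rows$component_type != "W"
    if (any(is.na(rows$gap_length[gaps])))
      stop("gap rows must carry gap_length (object ", obj, ")",
           call. = FALSE)
    if (any(gaps & (rows$object_end - rows$object_beg + 1L) !=
              rows$gap_length))
      stop("gap row span disagrees with gap_length (object ", obj, ")",
           call. = FALSE)
  }
  class(df) <- c("agp", "data.frame")
  df
}

#' Write AGP rows to file (AGP v2.0)
#'
#' @param rows an `agp` table from [agp_rows()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(rows, path) {
  rows <- agp_rows(as.data.frame(rows))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (r$component_type == "W") {
      fields <- c(r$object_id, r$object_beg, r$object_end,
                  r$part_number, "W", r$component_id,
                  r$component_beg, r$component_end, r$orientation)
    } else {
      linkage <- if (r$component_type == "U") "no" else "yes"
      evidence <- if (linkage == "yes") "map" else "na"
      fields <- c(r$object_id, r$object_beg, r$object_end,
                  r$part_number, r$component_type, r$gap_length,
                  "scaffold", linkage, evidence)
    }
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an AGP file
#'
#' @param path AGP file path.
#' @return an `agp` table.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(parts), function(i) {
    f <- parts[[i]]
    if (length(f) < 9)
      stop("AGP line ", i, ": expected 9 fields, got ", length(f),
           call. = FALSE)
    if (f[[5]] == "W") {
      data.frame(object_id = f[[1]], object_beg = as.integer(f[[2]]),
                 object_end = as.integer(f[[3]]),
                 part_number = as.integer(f[[4]]),
                 component_type = "W", component_id = f[[6]],
                 component_beg = as.integer(f[[7]]),
                 component_end = as.integer(f[[8]]),
                 orientation = f[[9]], gap_length = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(object_id = f[[1]], object_beg = as.integer(f[[2]]),
                 object_end = as.integer(f[[3]]),
                 part_number = as.integer(f[[4]]),
                 component_type = f[[5]], component_id = NA_character_,
                 component_beg = NA_integer_,
                 component_end = NA_integer_,
                 orientation = NA_character_,
                 gap_length = as.integer(f[[6]]),
                 stringsAsFactors = FALSE)
    }
  })
  agp_rows(do.call(rbind, rows))
}

#' Object lengths implied by an AGP table
#' @param rows an `agp` table.
#' @return named integer vector: object id to total length.
#' @export
agp_object_lengths <- function(rows) {
  out <- tapply(rows$object_end, rows$object_id, max)
  setNames(as.integer(out), names(out))
}
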