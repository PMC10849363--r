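#' Read and write GFF3 feature tables
#'
#' Features are carried internally as a tibble in 0-based half-open
#' coordinates; the 1-based inclusive convention of GFF3 is converted at this
#' boundary only. Attribute strings are parsed into a named-character
#' list-column.
#'
#' Records whose on-disk `end` is smaller than `start` are rejected with a
#' warning rather than an error. Comment and directive lines are skipped.
#'
#' @param path Path to a 9-column GFF3 file.
#' @return A tibble with columns `contig`, `source`, `ftype`, `start`, `end`
#'   (0-based half-open), `score`, `strand`, `frame`, `attributes` (list of
#'   named character vectors).
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(empty_features())
  parts <- stringi::stri_split_fixed(lines, "\t")
  ncols <- lengths(parts)
  if (any(ncols < 9)) {
    abort(paste0("GFF3 line(s) with fewer than 9 columns: line ",
                 which(ncols < 9)[1]))
  }
  m <- t(vapply(parts, function(p) p[1:9], character(9)))
  s <- suppressWarnings(as.integer(m[, 4]))
  e <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(s) || anyNA(e)) abort("non-integer coordinate in GFF3")
  bad <- e < s
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad), " GFF3 record(s) with end < start"))
  }
  keep <- !bad
  tibble(
    contig = m[keep, 1],
    source = m[keep, 2],
    ftype  = m[keep, 3],
    start  = s[keep] - 1L,
    end    = e[keep],
    score  = suppressWarnings(as.numeric(m[keep, 6])),
    strand = m[keep, 7],
    frame  = m[keep, 8],
    attributes = parse_gff_attributes(m[keep, 9])
  )
}

empty_features <- function() {
  tibble(contig = character(), source = character(), ftype = character(),
         start = integer(), end = integer(), score = numeric(),
         strand = character(), frame = character(), attributes = list())
}

parse_gff_attributes <- function(x) {
  lapply(x, function(a) {
    if (is.na(a) || a == "." || a == "") return(character())
    kv <- stringi::stri_split_fixed(strsplit(a, ";", fixed = TRUE)[[1]], "=", n = 2)
    kv <- kv[vapply(kv, function(p) nzchar(trimws(p[1])), logical(1))]
    setNames(vapply(kv, function(p) if (length(p) > 1) p[2] else "", character(1)),
             vapply(kv, function(p) trimws(p[1]), character(1)))
  })
}

format_gff_attributes <- function(attrs) {
  vapply(attrs, function(a) {
    if (length(a) == 0) return(".")
    paste(paste0(names(a), "=", a), collapse = ";")
  }, character(1))
}

#' @param features A feature tibble as returned by [read_gff3()].
#' @rdname read_gff3
#' @export
write_gff3 <- function(features, path) {
  score <- ifelse(is.na(features$score), ".", as.character(features$score))
  lines <- paste(features$contig,
                 features$source %||% ".",
                 features$ftype,
                 features$start + 1L,
                 features$end,
                 score,
                 features$strand,
                 features$frame %||% ".",
                 format_gff_attributes(features$attributes),
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Extract one attribute key from a feature tibble
#'
#' @param features A feature tibble.
#' @param key Attribute key, e.g. `"ID"` or `"Parent"`.
#' @return Character vector (NA where the key is absent).
#' @export
gff_attr <- function(features, key) {
  vapply(features$attributes, function(a) {
    if (key %in% names(a)) a[[key]] else NA_character_
  }, character(1))
}

#' Read a PAF whole-genome alignment file
#'
#' Maps the 12 core columns to fields; SAM-style tag columns are ignored.
#' Coordinates are already 0-based half-open in PAF and are kept as such.
#' Alignment identity is computed downstream as `matches / alnlen`.
#'
#' @param path Path to a PAF file.
#' @return A tibble with columns `qname`, `qlen`, `qstart`, `qend`, `strand`,
#'   `tname`, `tlen`, `tstart`, `tend`, `matches`, `alnlen`.
#' @export
read_paf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_paf())
  parts <- stringi::stri_split_fixed(lines, "\t")
  ncols <- lengths(parts)
  if (any(ncols < 12)) {
    abort(paste0("PAF line ", which(ncols < 12)[1], ": fewer than 12 columns"))
  }
  m <- t(vapply(parts, function(p) p[1:12], character(12)))
  int_cols <- c(2, 3, 4, 7, 8, 9, 10, 11)
  ints <- suppressWarnings(apply(m[, int_cols, drop = FALSE], 2, as.integer))
  ints <- matrix(ints, ncol = length(int_cols))
  if (anyNA(ints)) {
    bad_line <- which(apply(ints, 1, anyNA))[1]
    abort(paste0("PAF line ", bad_line, ": non-integer coordinate"))
  }
  tibble(
    qname = m[, 1], qlen = ints[, 1], qstart = ints[, 2], qend = ints[, 3],
    strand = m[, 5],
    tname = m[, 6], tlen = ints[, 4], tstart = ints[, 5], tend = ints[, 6],
    matches = ints[, 7], alnlen = ints[, 8]
  )
}

empty_paf <- function() {
  tibble(qname = character(), qlen = integer(), qstart = integer(),
         qend = integer(), strand = character(), tname = character(),
         tlen = integer(), tstart = integer(), tend = integer(),
         matches = integer(), alnlen = integer())
}

#' @param paf An alignment tibble as returned by [read_paf()].
#' @rdname read_paf
#' @export
write_paf <- function(paf, path) {
  lines <- paste(paf$qname, paf$qlen, paf$qstart, paf$qend, paf$strand,
                 paf$tname, paf$tlen, paf$tstart, paf$tend,
                 paf$matches, paf$alnlen, 60L, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a 12-column tabular alignment-hit file
#'
#' The classic 12-column tabular layout (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, E-value, bit score). Subject start may exceed subject end for
#' minus-strand hits; coordinates are kept 1-based as on disk. Extra columns
#' are ignored.
#'
#' @param path Path to the tabular hit file (no header).
#' @return A tibble with the 12 standard columns.
#' @export
read_hits <- function(path) {
  stopifnot(file.exists(path))
  cols <- c("query", "subject", "pct_identity", "aln_len", "mismatches",
            "gaps", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(as_tibble(setNames(
      c(list(character(), character()), rep(list(numeric()), 10)), cols)))
  }
  parts <- stringi::stri_split_fixed(lines, "\t")
  if (any(lengths(parts) < 12)) {
    abort(paste0("hit line ", which(lengths(parts) < 12)[1],
                 ": fewer than 12 columns"))
  }
  m <- t(vapply(parts, function(p) p[1:12], character(12)))
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10)
  if (anyNA(num)) abort("non-numeric value in tabular hit file")
  if (any(num[, 9] < 0)) abort("negative E-value in tabular hit file")
  tibble(query = m[, 1], subject = m[, 2], pct_identity = num[, 1],
         aln_len = as.integer(num[, 2]), mismatches = as.integer(num[, 3]),
         gaps = as.integer(num[, 4]), qstart = as.integer(num[, 5]),
         qend = as.integer(num[, 6]), sstart = as.integer(num[, 7]),
         send = as.integer(num[, 8]), evalue = num[, 9], bitscore = num[, 10])
}

#' @param hits A hit tibble.
#' @rdname read_hits
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits[, c("query", "subject", "pct_identity", "aln_len",
                            "mismatches", "gaps", "qstart", "qend", "sstart",
                            "send", "evalue", "bitscore")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a genetic-map table
#'
#' Tab-separated with header `marker  cross  linkage_group  cM` and an
#' optional `sequence` column.
#'
#' @param path Path to the map TSV.
#' @return A tibble with columns `marker`, `cross`, `linkage_group`, `cM`.
#' @export
read_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("marker", "cross", "linkage_group", "cM")
  if (!all(need %in% names(df))) {
    abort(paste0("map table must have columns: ", paste(need, collapse = ", ")))
  }
  cm <- suppressWarnings(as.numeric(df$cM))
  if (anyNA(cm)) {
    abort(paste0("non-numeric cM in map row ", which(is.na(cm))[1]))
  }
  tibble(marker = df$marker, cross = df$cross,
         linkage_group = df$linkage_group, cM = cm)
}

#' @param map A map tibble.
#' @rdname read_map
#' @export
write_map <- function(map, path) {
  readr::write_tsv(map[, c("marker", "cross", "linkage_group", "cM")], path)
  invisible(path)
}

#' Read a reference-guided scaffolding order table
#'
#' Tab-separated with header `scaffold  rank  contig  orientation`, giving
#' the order and orientation a reference-guided scaffolder assigned to each
#' contig.
#'
#' @param path Path to the order TSV.
#' @return A tibble with those four columns (`rank` integer).
#' @export
read_order <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("scaffold", "rank", "contig", "orientation")
  if (!all(need %in% names(df))) {
    abort(paste0("order table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  rank <- suppressWarnings(as.integer(df$rank))
  if (anyNA(rank)) abort("non-integer rank in order table")
  if (!all(df$orientation %in% c("+", "-", "?"))) {
    abort("order-table orientation must be one of +, -, ?")
  }
  tibble(scaffold = df$scaffold, rank = rank, contig = df$contig,
         orientation = df$orientation)
}

#' @param order_table An order tibble.
#' @rdname read_order
#' @export
write_order <- function(order_table, path) {
  readr::write_tsv(order_table[, c("scaffold", "rank", "contig",
                                   "orientation")], path)
  invisible(path)
}

#' Validate and write AGP v2.1
#'
#' The AGP tibble is wide: `scaffold`, `scaffold_start`, `scaffold_end`
#' (1-based inclusive), `part_number`, `component_type` (`W` contig, `U`
#' gap), then either `component_id`/`component_beg`/`component_end`/
#' `orientation` or `gap_length`/`gap_type`/`linkage`/`evidence`. Parts of a
#' scaffold must tile `[1, scaffold length]` without overlap; this is checked
#' before anything is written.
#'
#' @param agp An AGP tibble.
#' @param path Output path.
#' @param contig_lengths Optional named vector of component lengths used to
#'   check `W` row sub-ranges.
#' @return `write_agp()` invisibly returns `path`.
#' @export
write_agp <- function(agp, path, contig_lengths = NULL) {
  validate_agp(agp, contig_lengths)
  is_gap <- agp$component_type == "U"
  c6 <- ifelse(is_gap, as.character(agp$gap_length), agp$component_id)
  c7 <- ifelse(is_gap, agp$gap_type, as.character(agp$component_beg))
  c8 <- ifelse(is_gap, agp$linkage, as.character(agp$component_end))
  c9 <- ifelse(is_gap, agp$evidence, agp$orientation)
  lines <- paste(agp$scaffold, agp$scaffold_start, agp$scaffold_end,
                 agp$part_number, agp$component_type, c6, c7, c8, c9,
                 sep = "\t")
  writeLines(c("##agp-version 2.1", lines), path)
  invisible(path)
}

#' @rdname write_agp
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- stringi::stri_split_fixed(lines, "\t")
  m <- t(vapply(parts, function(p) p[1:9], character(9)))
  is_gap <- m[, 5] == "U"
  tibble(
    scaffold = m[, 1],
    scaffold_start = as.integer(m[, 2]),
    scaffold_end = as.integer(m[, 3]),
    part_number = as.integer(m[, 4]),
    component_type = m[, 5],
    component_id = ifelse(is_gap, NA_character_, m[, 6]),
    component_beg = ifelse(is_gap, NA, suppressWarnings(as.integer(m[, 7]))),
    component_end = ifelse(is_gap, NA, suppressWarnings(as.integer(m[, 8]))),
    orientation = ifelse(is_gap, NA_character_, m[, 9]),
    gap_length = ifelse(is_gap, suppressWarnings(as.integer(m[, 6])), NA),
    gap_type = ifelse(is_gap, m[, 7], NA_character_),
    linkage = ifelse(is_gap, m[, 8], NA_character_),
    evidence = ifelse(is_gap, m[, 9], NA_character_)
  )
}

#' @rdname write_agp
#' @export
validate_agp <- function(agp, contig_lengths = NULL) {
  for (sc in unique(agp$scaffold)) {
    rows <- agp[agp$scaffold == sc, ]
    rows <- rows[order(rows$part_number), ]
    if (!identical(rows$part_number, seq_len(nrow(rows)))) {
      abort(paste0("AGP scaffold ", sc, ": part numbers not 1..k"))
    }
    span <- rows$scaffold_end - rows$scaffold_start + 1L
    comp_len <- ifelse(rows$component_type == "U", rows$gap_length,
                       rows$component_end - rows$component_beg + 1L)
    expected_start <- c(1L, head(cumsum(span), -1) + 1L)
    bad <- which(rows$scaffold_start != expected_start | span != comp_len |
                   span < 1L)
    if (length(bad) > 0) {
      abort(paste0("AGP scaffold ", sc, ": tiling violation at part_number ",
                   paste(rows$part_number[bad], collapse = ", ")))
    }
    w <- rows[rows$component_type == "W", ]
    if (nrow(w) > 0) {
      if (any(is.na(w$component_id)) || any(w$component_beg < 1L) ||
          any(w$component_beg > w$component_end)) {
        abort(paste0("AGP scaffold ", sc, ": invalid W component range"))
      }
      if (!is.null(contig_lengths)) {
        unknown <- setdiff(w$component_id, names(contig_lengths))
        if (length(unknown) > 0) {
          abort(paste0("AGP references unknown contig(s): ",
                       paste(unknown, collapse = ", ")))
        }
        over <- w$component_end > contig_lengths[w$component_id]
        if (any(over)) {
          abort(paste0("AGP scaffold ", sc,
                       ": component range beyond contig length at part_number ",
                       paste(w$part_number[over], collapse = ", ")))
        }
      }
    }
  }
  invisible(agp)
}
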