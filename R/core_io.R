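#' Read a FASTA file
#'
#' Reads nucleotide (or amino-acid) sequences, uppercasing residues and
#' validating the alphabet. Nucleotide sequences may contain `A`, `C`,
#' `G`, `T` and `N`. Record ids (the first whitespace-delimited token of
#' the header) must be unique and every record must be non-empty.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` (default) or `"aa"`.
#' @return Named character vector of uppercased sequences; names are the
#'   record ids, the remainder of each header is kept in the
#'   `description` attribute.
#' @export
read_fasta <- function(path, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  empty <- which(Biostrings::width(set) == 0L)
  if (length(empty) > 0L) {
    stop("empty sequence for record ", empty[1L], " ('", ids[empty[1L]],
         "') in ", path)
  }
  if (any(ids == "")) stop("record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id '", ids[anyDuplicated(ids)], "' in ", path)
  }
  seqs <- toupper(as.character(set))
  bad_re <- if (alphabet == "dna") "[^ACGTN]" else "[^A-Z*-]"
  bad <- grepl(bad_re, seqs)
  if (any(bad)) {
    stop("invalid ", alphabet, " character in record '", ids[which(bad)[1L]],
         "' of ", path)
  }
  names(seqs) <- ids
  attr(seqs, "description") <- setNames(desc, ids)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences (an optional
#'   `description` attribute is appended to each header).
#' @param path Output path.
#' @param width Line wrap width (default 60 columns).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named")
  }
  desc <- attr(seqs, "description")
  headers <- names(seqs)
  if (!is.null(desc)) {
    has <- !is.na(desc[headers]) & desc[headers] != ""
    headers[has] <- paste(headers[has], desc[headers][has])
  }
  set <- Biostrings::BStringSet(setNames(as.character(seqs), headers))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Construct a repeat annotation table
#'
#' Annotations use 0-based half-open intervals (`length = end - start`)
#' on named scaffolds, a class drawn from [repeat_classes()], an optional
#' family id and a non-negative score (alignment identity fraction or
#' discovery support).
#'
#' @param scaffold Character vector of scaffold ids.
#' @param start,end Integer interval bounds, 0-based half-open.
#' @param repeat_class Classes; must all be in [repeat_classes()].
#' @param family_id Optional family ids (`NA` allowed).
#' @param score Non-negative numeric scores.
#' @param strand `"+"`, `"-"` or `"."`.
#' @return A `data.frame` with one row per annotation.
#' @export
repeat_annotation <- function(scaffold, start, end, repeat_class,
                              family_id = NA_character_, score = 0,
                              strand = ".") {
  n <- max(length(scaffold), length(start), length(end),
           length(repeat_class), length(family_id), length(score),
           length(strand))
  if (length(scaffold) == 0L) n <- 0L
  ann <- data.frame(
    scaffold = rep_len(as.character(scaffold), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    repeat_class = rep_len(as.character(repeat_class), n),
    family_id = rep_len(as.character(family_id), n),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
  validate_annotations(ann)
  ann
}

validate_annotations <- function(ann, scaffold_lengths = NULL) {
  stopifnot(is.data.frame(ann))
  need <- c("scaffold", "start", "end", "repeat_class", "family_id", "score")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(ann) == 0L) return(invisible(ann))
  if (any(ann$start < 0L) || any(ann$end <= ann$start)) {
    stop("invalid interval: need 0 <= start < end")
  }
  bad <- !ann$repeat_class %in% REPEAT_CLASSES
  if (any(bad)) {
    stop("unknown repeat class '", ann$repeat_class[which(bad)[1L]],
         "' (see repeat_classes())")
  }
  if (any(!is.finite(ann$score)) || any(ann$score < 0)) {
    stop("scores must be finite and >= 0")
  }
  if (!is.null(scaffold_lengths)) {
    len <- scaffold_lengths[ann$scaffold]
    if (any(is.na(len))) {
      stop("annotation on unknown scaffold '",
           ann$scaffold[which(is.na(len))[1L]], "'")
    }
    over <- ann$end > len
    if (any(over)) {
      stop("interval exceeds scaffold length on '",
           ann$scaffold[which(over)[1L]], "'")
    }
  }
  invisible(ann)
}

sort_annotations <- function(ann) {
  ann[order(ann$scaffold, ann$start, ann$end), , drop = FALSE]
}

#' Write repeat annotations as GFF3 or BED
#'
#' BED output is 0-based half-open (BED6: name carries
#' `class|family_id`); GFF3 output is 1-based closed with the repeat
#' class in the type column and the family id as an attribute. Rows are
#' sorted deterministically by (scaffold, start, end).
#'
#' @param ann Annotation table (see [repeat_annotation()]).
#' @param path Output path.
#' @param dialect `"GFF3"` or `"BED"`.
#' @param scaffold_lengths Optional named vector used to validate that
#'   intervals do not exceed their scaffold.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(ann, path, dialect = c("GFF3", "BED"),
                              scaffold_lengths = NULL) {
  dialect <- match.arg(dialect)
  validate_annotations(ann, scaffold_lengths)
  ann <- sort_annotations(ann)
  fam <- ifelse(is.na(ann$family_id) | ann$family_id == "", ".", ann$family_id)
  strand <- if ("strand" %in% names(ann)) ann$strand else "."
  if (dialect == "BED") {
    lines <- sprintf("%s\t%d\t%d\t%s|%s\t%s\t%s",
                     ann$scaffold, ann$start, ann$end,
                     ann$repeat_class, fam,
                     format_score(ann$score), strand)
  } else {
    attrs <- sprintf("ID=rep%06d;family_id=%s", seq_len(max(nrow(ann), 1L)), fam)
    if (nrow(ann) == 0L) attrs <- character(0)
    lines <- c("##gff-version 3",
               sprintf("%s\trepeatscape\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                       ann$scaffold, ann$repeat_class,
                       ann$start + 1L, ann$end,
                       format_score(ann$score), strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

format_score <- function(x) {
  ifelse(is.na(x), ".", formatC(x, format = "g", digits = 6))
}

#' Read repeat annotations from GFF3 or BED
#'
#' Inverse of [write_annotations()] for the fields both formats carry
#' (scaffold, start, end, class, family, score, strand). Coordinates are
#' returned 0-based half-open regardless of the on-disk convention.
#'
#' @param path Input path.
#' @param dialect `"auto"` (by pragma/extension), `"GFF3"` or `"BED"`.
#' @return Annotation `data.frame`.
#' @export
read_annotations <- function(path, dialect = c("auto", "GFF3", "BED")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "auto") {
    dialect <- if (length(lines) > 0L && grepl("^##gff-version", lines[1L])) {
      "GFF3"
    } else if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "GFF3" else "BED"
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(repeat_annotation(character(0), integer(0), integer(0),
                             character(0))[0, ])
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "BED") {
    name <- vapply(f, `[`, "", 4L)
    parts <- strsplit(name, "|", fixed = TRUE)
    ann <- repeat_annotation(
      scaffold = vapply(f, `[`, "", 1L),
      start = as.integer(vapply(f, `[`, "", 2L)),
      end = as.integer(vapply(f, `[`, "", 3L)),
      repeat_class = vapply(parts, `[`, "", 1L),
      family_id = ifelse(vapply(parts, function(p) p[2L] %||% ".", "") == ".",
                         NA_character_,
                         vapply(parts, function(p) p[2L] %||% ".", "")),
      score = parse_score(vapply(f, `[`, "", 5L)),
      strand = vapply(f, `[`, "", 6L)
    )
  } else {
    attrs <- vapply(f, `[`, "", 9L)
    fam <- sub("^.*family_id=([^;]*).*$", "\\1", attrs)
    fam[!grepl("family_id=", attrs)] <- "."
    ann <- repeat_annotation(
      scaffold = vapply(f, `[`, "", 1L),
      start = as.integer(vapply(f, `[`, "", 4L)) - 1L,
      end = as.integer(vapply(f, `[`, "", 5L)),
      repeat_class = vapply(f, `[`, "", 3L),
      family_id = ifelse(fam == ".", NA_character_, fam),
      score = parse_score(vapply(f, `[`, "", 6L)),
      strand = vapply(f, `[`, "", 7L)
    )
  }
  ann
}

parse_score <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[x == "."] <- NA_real_
  out
}

#' Read a per-element coverage table
#'
#' Reads a TSV with an `element_id` column and one numeric mean-coverage
#' column per library (e.g. `genome`, `flower`, `root_stem`). All values
#' must be finite and non-negative; missing values are rejected.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with `element_id` plus the library columns.
#' @export
read_coverage_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"element_id" %in% names(tab)) {
    stop("coverage table must have an 'element_id' column")
  }
  libs <- setdiff(names(tab), "element_id")
  if (length(libs) == 0L) stop("coverage table has no library columns")
  if (anyDuplicated(tab$element_id)) {
    stop("duplicate element_id '", tab$element_id[anyDuplicated(tab$element_id)],
         "' in coverage table")
  }
  for (lb in libs) {
    v <- tab[[lb]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0L) {
      stop("non-numeric, missing or negative coverage for element '",
           tab$element_id[bad[1L]], "' in column '", lb, "'")
    }
    tab[[lb]] <- v
  }
  tab
}
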