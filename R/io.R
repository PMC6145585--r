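#' Read a FASTA file
#'
#' Reads multi-record FASTA via Biostrings, upper-cases the sequences and
#' rejects duplicate record ids (reporting the offending header line
#' numbers). The record id is the first whitespace-delimited token of the
#' header.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    lines <- grep("^>", readLines(path))
    headers <- sub("\\s.*$", "", sub("^>", "", readLines(path)[lines]))
    where <- lines[headers %in% dup]
    stop("duplicate record id(s) ", paste(dup, collapse = ", "),
         " at line(s) ", paste(where, collapse = ", "))
  }
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq_", seq_along(sequences))
  set <- Biostrings::DNAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a count matrix file
#'
#' Accepts the two layouts in which published count matrices circulate:
#' four base-labelled rows (`A 1 2 3 ...`, JASPAR-style brackets
#' tolerated) or a four-column table with an `A C G T` header, one row
#' per position. An optional leading `>name` header supplies the factor
#' name; otherwise the file stem is used.
#'
#' @param path File path.
#' @param tf_name Optional factor name overriding header/stem.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, tf_name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- if (!is.null(tf_name)) tf_name else
    sub("\\.[^.]*$", "", basename(path))
  if (length(lines) && startsWith(lines[1], ">")) {
    if (is.null(tf_name)) name <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  if (!length(lines)) stop(path, ": no matrix rows found")
  toks <- lapply(lines, function(l)
    strsplit(gsub("[][|]", " ", l), "\\s+")[[1]])
  first <- toupper(toks[[1]])
  parse_num <- function(cells, line_no) {
    v <- suppressWarnings(as.numeric(cells))
    if (anyNA(v))
      stop(path, " line ", line_no, ": non-numeric cell '",
           cells[which(is.na(v))[1]], "'")
    v
  }
  if (identical(first, DNA_BASES)) {
    # header A C G T, one row per position
    counts <- do.call(rbind, lapply(seq_along(toks[-1]), function(i)
      parse_num(toks[[i + 1L]], i + 1L)))
    colnames(counts) <- DNA_BASES
  } else if (first[1] %in% DNA_BASES && length(lines) >= 4L) {
    # base-labelled rows: one row per base, one column per position
    rows <- list()
    for (i in seq_along(lines)) {
      cells <- toks[[i]]
      base <- toupper(cells[1])
      if (!base %in% DNA_BASES)
        stop(path, " line ", i, ": expected a base label, got '",
             cells[1], "'")
      rows[[base]] <- parse_num(cells[-1], i)
    }
    if (!all(DNA_BASES %in% names(rows)))
      stop(path, ": missing base row(s) ",
           paste(setdiff(DNA_BASES, names(rows)), collapse = ", "))
    counts <- cbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
  } else {
    stop(path, ": unrecognised layout; expected base-labelled rows or ",
         "an 'A C G T' header")
  }
  count_matrix(name, counts)
}

#' Read an expression pointcloud CSV
#'
#' One row per nucleus; required columns `embryo_id`, `genotype`,
#' `timepoint`, `ap`, `dv`; every remaining column is an expression
#' channel. One file may hold many embryos; rows are split by
#' `embryo_id` and each embryo validated on load.
#'
#' @param path CSV path.
#' @return A list of [pointcloud()]s, one per embryo.
#' @export
read_pointcloud_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("embryo_id", "genotype", "timepoint", "ap", "dv")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing required column(s) ",
         paste(missing, collapse = ", "))
  channels <- setdiff(names(df), required)
  if (!length(channels))
    stop(path, ": no channel columns beyond ",
         paste(required, collapse = ", "))
  lapply(split(df, df$embryo_id), function(sub) {
    pointcloud(sub$embryo_id[1], sub$genotype[1], sub$timepoint[1],
               sub[, c("ap", "dv", channels), drop = FALSE])
  })
}

#' Write a cohort of pointclouds to CSV
#'
#' @param cohort List of [pointcloud()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pointcloud_csv <- function(cohort, path) {
  rows <- lapply(cohort, function(pc) {
    cbind(data.frame(embryo_id = pc$embryo_id, genotype = pc$genotype,
                     timepoint = pc$timepoint, stringsAsFactors = FALSE),
          pc$nuclei)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write motif hits as BED6 and/or CSV
#'
#' BED6 columns: sequence id, start, end, factor name, score, strand
#' (0-based half-open, matching the hit table). The CSV keeps the score
#' and p-value columns.
#'
#' @param hits A hit data.frame from [scan_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$sequence_id, hits$start, hits$end, hits$tf_name,
                    round(hits$score, 4), hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_bed
#' @export
write_hits_csv <- function(hits, path) {
  write.csv(hits, path, row.names = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' A run configuration collects the paths and tunable parameters of a
#' full analysis (matrices, sequences, pointclouds, output directory,
#' pseudocount, background, p-value cutoff, granularity, strips, stripe
#' windows, cohort definitions, seed). Paths listed under `paths` are
#' checked for existence at load time.
#'
#' @param path YAML file path.
#' @param check_paths Verify that entries under `paths` exist;
#'   default TRUE.
#' @return A named list with class `run_config`.
#' @export
read_run_config <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (check_paths && !is.null(cfg$paths)) {
    for (nm in names(cfg$paths)) {
      p <- cfg$paths[[nm]]
      if (is.character(p) && length(p) == 1L && !file.exists(p))
        stop("config path '", nm, "' does not exist: ", p)
    }
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config` (or plain list) to serialize.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
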