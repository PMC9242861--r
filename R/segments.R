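## Canonical chromosome sort order: 1..22, X, Y, then anything else.
chrom_order <- function(x) {
  x <- as.character(x)
  known <- c(as.character(1:22), "X", "Y")
  i <- match(x, known)
  i[is.na(i)] <- length(known) + as.integer(factor(x[is.na(i)]))
  i
}

normalize_chrom <- function(x, policy = c("strip", "add", "keep")) {
  policy <- match.arg(policy)
  x <- as.character(x)
  if (policy == "strip") sub("^chr", "", x)
  else if (policy == "add") ifelse(grepl("^chr", x), x, paste0("chr", x))
  else x
}

#' Construct an allele-specific copy-number profile
#'
#' A profile holds one sample's integer allele-specific segments
#' (major allele A >= minor allele B >= 0), sorted and non-overlapping
#' within each chromosome, with 1-based inclusive coordinates.
#' Rows where `minor_cn > major_cn` are swapped (alleles are unordered)
#' with a warning.
#'
#' @param sample_id sample identifier.
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `major_cn`, `minor_cn`.
#' @param genome optional `cn_genome` the coordinates refer to.
#' @return object of class `cn_profile`.
#' @export
cn_profile <- function(sample_id, segments, genome = NULL) {
  need <- c("chrom", "start", "end", "major_cn", "minor_cn")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("missing segment column(s): ", paste(miss, collapse = ", "))
  seg <- segments[, need, drop = FALSE]
  seg$chrom <- as.character(seg$chrom)
  for (col in c("start", "end", "major_cn", "minor_cn")) {
    v <- seg[[col]]
    if (any(is.na(v)) || any(v != round(v)))
      stop("non-integer values in column '", col, "' for sample ", sample_id)
    seg[[col]] <- as.numeric(round(v))
  }
  if (any(seg$major_cn < 0 | seg$minor_cn < 0))
    stop("negative allele copy numbers for sample ", sample_id)
  if (any(seg$start > seg$end))
    stop("segment with start > end for sample ", sample_id)
  sw <- seg$minor_cn > seg$major_cn
  if (any(sw)) {
    tmp <- seg$major_cn[sw]
    seg$major_cn[sw] <- seg$minor_cn[sw]
    seg$minor_cn[sw] <- tmp
    warning(sum(sw), " segment(s) with minor_cn > major_cn swapped for sample ",
            sample_id, call. = FALSE)
  }
  seg <- seg[order(chrom_order(seg$chrom), seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  ## overlap check within chromosome
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      i <- which(s$start[-1] <= s$end[-nrow(s)])[1]
      stop("overlapping segments for sample ", sample_id, " on chromosome ",
           ch, " near position ", s$start[i + 1])
    }
  }
  structure(list(sample_id = as.character(sample_id), segments = seg,
                 genome = genome),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat("cn_profile '", x$sample_id, "': ", nrow(x$segments), " segments on ",
      length(unique(x$segments$chrom)), " chromosomes\n", sep = "")
  invisible(x)
}

segment_lengths <- function(profile) {
  with(profile$segments, end - start + 1)
}

#' Read allele-specific segment tables
#'
#' Reads a multi-sample segment table and splits it into one [cn_profile]
#' per sample. Two dialects are supported: `ascat` (tab-separated with header
#' `sample chr startpos endpos nMajor nMinor`, 1-based inclusive) and
#' `bed_like` (`chrom start end sample major_cn minor_cn`, 0-based
#' half-open, converted at the boundary).
#'
#' @param path input file.
#' @param dialect `"ascat"` or `"bed_like"`.
#' @param genome optional `cn_genome` attached to each profile.
#' @param chr_prefix chromosome-name policy: `"strip"` (default), `"add"`,
#'   or `"keep"`.
#' @param include_y keep chromosome Y rows (default drop).
#' @return named list of `cn_profile`, ordered by sample id.
#' @export
read_segments <- function(path, dialect = c("ascat", "bed_like"), genome = NULL,
                          chr_prefix = "strip", include_y = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  cols <- switch(dialect,
    ascat    = c(sample = "sample", chrom = "chr", start = "startpos",
                 end = "endpos", major_cn = "nMajor", minor_cn = "nMinor"),
    bed_like = c(chrom = "chrom", start = "start", end = "end",
                 sample = "sample", major_cn = "major_cn",
                 minor_cn = "minor_cn"))
  miss <- setdiff(unname(cols), names(tab))
  if (length(miss))
    stop("missing column(s) for dialect '", dialect, "': ",
         paste(miss, collapse = ", "))
  df <- data.frame(sample  = tab[[cols["sample"]]],
                   chrom   = normalize_chrom(tab[[cols["chrom"]]], chr_prefix),
                   start   = suppressWarnings(as.numeric(tab[[cols["start"]]])),
                   end     = suppressWarnings(as.numeric(tab[[cols["end"]]])),
                   major_cn = suppressWarnings(as.numeric(tab[[cols["major_cn"]]])),
                   minor_cn = suppressWarnings(as.numeric(tab[[cols["minor_cn"]]])),
                   stringsAsFactors = FALSE)
  if (dialect == "bed_like") df$start <- df$start + 1  # 0-based half-open -> 1-based incl.
  bad <- is.na(df$major_cn) | is.na(df$minor_cn) |
    df$major_cn != round(df$major_cn) | df$minor_cn != round(df$minor_cn)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-integer allele counts rejected",
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  if (!include_y) df <- df[!(sub("^chr", "", df$chrom) %in% "Y"), , drop = FALSE]
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  ids <- unique(df$sample)
  profiles <- lapply(ids, function(id)
    cn_profile(id, df[df$sample == id, -1, drop = FALSE], genome = genome))
  names(profiles) <- ids
  profiles[order(ids)]
}

#' Write segment profiles
#'
#' Inverse of [read_segments()]: rows ordered by (sample, chromosome, start),
#' coordinates converted back for the `bed_like` dialect, so that a
#' write/read round trip reproduces every field.
#'
#' @param profiles list of `cn_profile` (or a single one).
#' @param path output file.
#' @param dialect `"ascat"` or `"bed_like"`.
#' @export
write_segments <- function(profiles, path, dialect = c("ascat", "bed_like")) {
  dialect <- match.arg(dialect)
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p)
    cbind(sample = p$sample_id, p$segments, stringsAsFactors = FALSE))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), chrom = character(), start = numeric(),
               end = numeric(), major_cn = numeric(), minor_cn = numeric())
  df <- df[order(df$sample, chrom_order(df$chrom), df$start), , drop = FALSE]
  out <- switch(dialect,
    ascat = data.frame(sample = df$sample, chr = df$chrom,
                       startpos = df$start, endpos = df$end,
                       nMajor = df$major_cn, nMinor = df$minor_cn),
    bed_like = data.frame(chrom = df$chrom, start = df$start - 1, end = df$end,
                          sample = df$sample, major_cn = df$major_cn,
                          minor_cn = df$minor_cn))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge abutting segments with identical copy number
#'
#' Contiguous neighbours on a chromosome sharing `(major_cn, minor_cn)` are
#' combined into a single segment; total covered length is preserved and the
#' operation is idempotent.
#'
#' @param profile a `cn_profile`.
#' @return merged `cn_profile`.
#' @export
merge_adjacent <- function(profile) {
  seg <- profile$segments
  if (nrow(seg) < 2) return(profile)
  keep <- logical(nrow(seg))
  keep[1] <- TRUE
  j <- 1
  for (i in 2:nrow(seg)) {
    same <- seg$chrom[i] == seg$chrom[j] &&
      seg$start[i] == seg$end[j] + 1 &&
      seg$major_cn[i] == seg$major_cn[j] &&
      seg$minor_cn[i] == seg$minor_cn[j]
    if (same) {
      seg$end[j] <- seg$end[i]
    } else {
      keep[i] <- TRUE
      j <- i
    }
  }
  profile$segments <- seg[keep, , drop = FALSE]
  rownames(profile$segments) <- NULL
  profile
}

#' Validate a profile against its invariants
#'
#' Report-only check of segment invariants (coordinates ordered, alleles
#' ordered and non-negative, segments sorted and non-overlapping, ends within
#' chromosome lengths, chromosomes known to the genome). A clean profile
#' yields a zero-row report.
#'
#' @param profile a `cn_profile` or a bare list with a `segments` data.frame.
#' @param genome optional `cn_genome` (defaults to `profile$genome`).
#' @return data.frame with columns `sample`, `chrom`, `position`, `rule`,
#'   `message`.
#' @export
validate_profile <- function(profile, genome = NULL) {
  if (is.null(genome)) genome <- profile$genome
  seg <- profile$segments
  id <- profile$sample_id
  rep0 <- function(chrom, pos, rule, msg)
    data.frame(sample = id, chrom = chrom, position = pos, rule = rule,
               message = msg, stringsAsFactors = FALSE)
  out <- list()
  bad <- which(seg$start > seg$end)
  for (i in bad) out[[length(out) + 1]] <-
    rep0(seg$chrom[i], seg$start[i], "start_le_end", "segment start > end")
  bad <- which(seg$minor_cn > seg$major_cn)
  for (i in bad) out[[length(out) + 1]] <-
    rep0(seg$chrom[i], seg$start[i], "allele_order", "minor_cn > major_cn")
  bad <- which(seg$major_cn < 0 | seg$minor_cn < 0)
  for (i in bad) out[[length(out) + 1]] <-
    rep0(seg$chrom[i], seg$start[i], "non_negative", "negative copy number")
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (nrow(s) > 1) {
      if (is.unsorted(s$start))
        out[[length(out) + 1]] <- rep0(ch, s$start[1], "sorted",
                                       "segments not sorted by start")
      ov <- which(s$start[-1] <= s$end[-nrow(s)])
      for (i in ov) out[[length(out) + 1]] <-
        rep0(ch, s$start[i + 1], "non_overlapping",
             sprintf("segments [%d,%d] and [%d,%d] overlap",
                     s$start[i], s$end[i], s$start[i + 1], s$end[i + 1]))
    }
    if (!is.null(genome)) {
      len <- chrom_length(genome, ch)
      if (is.na(len)) {
        out[[length(out) + 1]] <- rep0(ch, NA, "chrom_known",
                                       "chromosome not in genome")
      } else {
        ob <- which(s$end > len)
        for (i in ob) out[[length(out) + 1]] <-
          rep0(ch, s$end[i], "within_chrom",
               sprintf("segment end %d beyond chromosome length %d",
                       s$end[i], as.integer(len)))
      }
    }
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(),
                      position = numeric(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
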