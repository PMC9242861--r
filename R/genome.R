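#' Load a genome definition
#'
#' A genome definition holds chromosome lengths and p/q arm boundaries.
#' Fixed hg19 and hg38 tables ship with the package; custom genomes can be
#' loaded from a two-to-four-column TSV (`chrom  length  [p_end  q_start]`).
#'
#' @param build `"hg19"`, `"hg38"`, or a path to a genome TSV.
#' @param include_x include chromosome X (default `TRUE`).
#' @param include_y include chromosome Y (default `FALSE`).
#' @return an object of class `cn_genome`: a list with `chrom` (data.frame of
#'   `chrom`, `length`, `p_end`, `q_start`) and `build`.
#' @export
load_genome <- function(build = "hg19", include_x = TRUE, include_y = FALSE) {
  path <- if (file.exists(build)) build else
    system.file("extdata", paste0("genome_", build, ".tsv"), package = "cnsig")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown genome build or missing genome file: ", build)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  if (!all(c("chrom", "length") %in% names(tab)))
    stop("genome file must have columns 'chrom' and 'length'")
  if (is.null(tab$p_end)) tab$p_end <- NA_real_
  if (is.null(tab$q_start)) tab$q_start <- NA_real_
  if (any(tab$length <= 0)) stop("chromosome lengths must be positive")
  bad <- !is.na(tab$p_end) &
    (tab$p_end <= 0 | tab$q_start <= tab$p_end | tab$q_start > tab$length)
  if (any(bad)) stop("arm boundaries outside chromosome: ",
                     paste(tab$chrom[bad], collapse = ", "))
  if (!include_x) tab <- tab[tab$chrom != "X", ]
  if (!include_y) tab <- tab[tab$chrom != "Y", ]
  structure(list(chrom = tab, build = if (file.exists(build)) "custom" else build),
            class = "cn_genome")
}

#' @export
print.cn_genome <- function(x, ...) {
  cat("cn_genome <", x$build, ">: ", nrow(x$chrom), " chromosomes, ",
      format(sum(x$chrom$length), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(as.character(chrom), genome$chrom$chrom)
  genome$chrom$length[i]
}

#' Chromosome-arm intervals of a genome
#'
#' @param genome a `cn_genome`.
#' @return data.frame with `chrom`, `arm` ("p"/"q"), `start`, `end`
#'   (1-based inclusive). Chromosomes without arm boundaries contribute a
#'   single whole-chromosome "q" row.
#' @export
genome_arms <- function(genome) {
  tab <- genome$chrom
  out <- lapply(seq_len(nrow(tab)), function(i) {
    if (is.na(tab$p_end[i])) {
      data.frame(chrom = tab$chrom[i], arm = "q", start = 1,
                 end = tab$length[i], stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = tab$chrom[i], arm = c("p", "q"),
                 start = c(1, tab$q_start[i]),
                 end = c(tab$p_end[i], tab$length[i]),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
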