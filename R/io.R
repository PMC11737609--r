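#' @name plot_csv
#' @title Plot-level CSV interchange
#' @description
#' The canonical plot table has columns `env`, `rep`, `block`, `entry`,
#' `parent1`, `parent2`, `is_check`, then one numeric column per trait.
#' Ordinal damage scores (FD1, FD2, FD3, ED) are validated against the 1-9
#' scale on read. Empty cells become NA; CRLF and LF files parse
#' identically.
NULL

.ordinal_traits <- c("FD1", "FD2", "FD3", "ED")

#' Read a plot-level CSV
#'
#' @param path File path.
#' @return Plot data frame (see [simulate_trial()] for the layout).
#' @export
read_plot_csv <- function(path) {
  required <- c("env", "rep", "block", "entry", "parent1", "parent2")
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!"is_check" %in% names(d)) d$is_check <- is.na(d$parent1)
  d$is_check <- as.logical(d$is_check)
  meta <- c(required, "is_check", "plot")
  trait_cols <- setdiff(names(d), meta)
  for (tc in trait_cols) {
    v <- d[[tc]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad))
        stop("non-numeric value in column '", tc, "', data row ", bad[1],
             ": '", v[bad[1]], "'")
      d[[tc]] <- vn
    }
    if (tc %in% .ordinal_traits) {
      out_of_scale <- which(!is.na(d[[tc]]) &
                              (d[[tc]] < 1 | d[[tc]] > 9 |
                                 d[[tc]] != round(d[[tc]])))
      if (length(out_of_scale))
        stop("column '", tc, "' must hold integer scores in 1-9; data row ",
             out_of_scale[1], " has ", d[[tc]][out_of_scale[1]])
    }
  }
  d
}

#' Write a plot-level CSV
#'
#' @param plots Plot data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_plot_csv <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a marker panel
#'
#' @param markers A `marker_matrix`.
#' @param path File path.
#' @param format `"hapmap"` (tab-delimited: rs, alleles, chrom, pos, one
#'   column per parent, diploid letter codes AA/BB with NN for missing) or
#'   `"vcf"` (minimal VCF with GT-only FORMAT).
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path, format = c("hapmap", "vcf")) {
  format <- match.arg(format)
  g <- markers$geno
  map <- markers$map
  if (format == "hapmap") {
    code <- matrix("NN", nrow(g), ncol(g))
    code[!is.na(g) & g == 0] <- "AA"
    code[!is.na(g) & g == 2] <- "BB"
    tab <- data.frame(rs = map$snp, alleles = map$alleles,
                      chrom = map$chrom, pos = map$pos,
                      t(code), check.names = FALSE,
                      stringsAsFactors = FALSE)
    names(tab)[-(1:4)] <- rownames(g)
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(g)),
                       collapse = "\t")), con)
    gt <- matrix("./.", nrow(g), ncol(g))
    gt[!is.na(g) & g == 0] <- "0/0"
    gt[!is.na(g) & g == 2] <- "1/1"
    for (m in seq_len(ncol(g))) {
      writeLines(paste(c(map$chrom[m], map$pos[m], map$snp[m], "A", "B",
                         ".", "PASS", ".", "GT", gt[, m]),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a marker panel
#'
#' Accepts the HapMap-style tab table or a minimal GT-only VCF and returns
#' the unified 0/2/NA inbred dosage coding. Heterozygous calls are
#' impossible in fully inbred parents, so they are set missing and counted
#' in a warning.
#'
#' @param path File path.
#' @param format `"hapmap"` or `"vcf"`; default guesses from the first
#'   line.
#' @return A `marker_matrix` (without causal-effect annotation).
#' @export
read_markers <- function(path, format = c("auto", "hapmap", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, "##fileformat=VCF")) "vcf" else "hapmap"
  }
  n_het <- 0L
  if (format == "hapmap") {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             comment.char = "")
    parents <- names(tab)[-(1:4)]
    code <- as.matrix(tab[, parents, drop = FALSE])
    g <- matrix(NA_real_, ncol(code), nrow(code),
                dimnames = list(parents, tab$rs))
    g[t(code == "AA")] <- 0
    g[t(code == "BB")] <- 2
    het <- t(code == "AB" | code == "BA")
    n_het <- sum(het, na.rm = TRUE)
    map <- data.frame(snp = tab$rs, chrom = as.character(tab$chrom),
                      pos = tab$pos, alleles = tab$alleles,
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "##")]
    header <- strsplit(body[1], "\t")[[1]]
    parents <- header[-(1:9)]
    rows <- strsplit(body[-1], "\t")
    n_snp <- length(rows)
    g <- matrix(NA_real_, length(parents), n_snp)
    rownames(g) <- parents
    map <- data.frame(snp = character(n_snp), chrom = character(n_snp),
                      pos = numeric(n_snp), alleles = character(n_snp),
                      stringsAsFactors = FALSE)
    for (m in seq_len(n_snp)) {
      f <- rows[[m]]
      map$snp[m] <- f[3]; map$chrom[m] <- f[1]
      map$pos[m] <- as.numeric(f[2])
      map$alleles[m] <- paste(f[4], f[5], sep = "/")
      gt <- sub(":.*", "", f[-(1:9)])
      val <- rep(NA_real_, length(gt))
      val[gt %in% c("0/0", "0|0")] <- 0
      val[gt %in% c("1/1", "1|1")] <- 2
      het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
      n_het <- n_het + sum(het)
      g[, m] <- val
    }
    colnames(g) <- map$snp
  }
  if (n_het > 0)
    warning(n_het, " heterozygous call(s) in inbred parents set to missing")
  structure(list(geno = g, map = map,
                 causal = data.frame(snp = character(0), effect = numeric(0)),
                 parent_values = stats::setNames(rep(NA_real_, nrow(g)),
                                                 rownames(g))),
            class = "marker_matrix")
}

#' Write / read the ground-truth sidecar of a simulated study
#'
#' Long-format plain-text table (component, trait, name, value) recording
#' the simulated true effects, for parameter-recovery checks.
#'
#' @param genetics Named list of `true_genetics` (one per trait).
#' @param path File path.
#' @return `path` invisibly (`write_truth`); a data frame (`read_truth`).
#' @export
write_truth <- function(genetics, path) {
  rows <- list()
  for (trait in names(genetics)) {
    g <- genetics[[trait]]
    add <- function(component, name, value)
      rows[[length(rows) + 1L]] <<- data.frame(
        component = component, trait = trait, name = name, value = value,
        stringsAsFactors = FALSE)
    add("mu", "mu", g$mu)
    add("var_error", "var_error", g$var_error)
    for (nm in names(g$gca)) add("gca", nm, g$gca[[nm]])
    for (nm in names(g$sca)) add("sca", nm, g$sca[[nm]])
    for (nm in names(g$env_effects)) add("env", nm, g$env_effects[[nm]])
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
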