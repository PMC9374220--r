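#' Construct a genotype table
#'
#' A `genotype_table` holds diploid, codominant multilocus genotypes for a
#' set of individuals, each assigned to a population. Allele calls are
#' positive integer codes; missing genotypes are `NA`. This is the input for
#' expected-heterozygosity estimation and population-graph construction.
#'
#' @param individuals character vector of individual identifiers.
#' @param populations character vector of population labels, one per
#'   individual.
#' @param loci character vector of locus names.
#' @param allele1,allele2 integer matrices (individuals x loci) holding the
#'   two allele codes of each genotype; both `NA` where the genotype is
#'   missing. Allele order within a genotype carries no meaning.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(individuals, populations, loci, allele1, allele2) {
  individuals <- as.character(individuals)
  populations <- as.character(populations)
  loci <- as.character(loci)
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  n <- length(individuals)
  if (length(populations) != n)
    stop("'populations' must have one label per individual")
  if (any(is.na(populations)) || any(populations == ""))
    stop("every individual needs a non-empty population label")
  if (!identical(dim(allele1), dim(allele2)))
    stop("'allele1' and 'allele2' must have identical dimensions")
  if (nrow(allele1) != n || ncol(allele1) != length(loci))
    stop("allele matrices must be individuals x loci")
  # half-missing genotypes are not representable: either both alleles or none
  half <- xor(is.na(allele1), is.na(allele2))
  if (any(half))
    stop("genotypes must be missing as a pair: found half-missing calls")
  ok1 <- allele1[!is.na(allele1)]
  ok2 <- allele2[!is.na(allele2)]
  if (any(ok1 <= 0) || any(ok2 <= 0) ||
      any(ok1 != round(ok1)) || any(ok2 != round(ok2)))
    stop("allele codes must be positive integers")
  dimnames(allele1) <- dimnames(allele2) <- list(individuals, loci)
  structure(
    list(individuals = individuals, populations = populations, loci = loci,
         allele1 = allele1, allele2 = allele2),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d populations, %d loci\n",
              length(x$individuals), length(unique(x$populations)),
              length(x$loci)))
  miss <- mean(is.na(x$allele1))
  cat(sprintf("missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals per population
#' @param table a [genotype_table()].
#' @return named integer vector.
#' @export
population_sizes <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  tab <- table(table$populations)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read genotypes from a GenePop file
#'
#' Parses the GenePop text format (2- or 3-digit allele coding). The file
#' starts with a title line, then one line per locus (or a single
#' comma-separated locus line), then `POP` blocks of individual lines
#' `name , 0101 0202 ...`. Codes `00`/`000` denote missing alleles.
#'
#' @param path path to a GenePop file.
#' @param pop_labels how to label populations: `"first_individual"` (the
#'   name of the first individual in each POP block, the common convention)
#'   or `"sequential"` (`pop1`, `pop2`, ...).
#' @return a [genotype_table()].
#' @export
read_genepop <- function(path, pop_labels = c("first_individual", "sequential")) {
  pop_labels <- match.arg(pop_labels)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != "" | seq_along(lines) == 1L]
  if (length(lines) < 3L)
    stop("GenePop parse error: file too short (need title, loci, POP)")
  pop_idx <- which(toupper(trimws(lines)) == "POP")
  if (length(pop_idx) == 0L)
    stop("GenePop parse error: no POP line found")
  header <- lines[2:(pop_idx[1] - 1L)]
  if (length(header) == 1L && grepl(",", header))
    loci <- trimws(strsplit(header, ",")[[1]])
  else
    loci <- trimws(header)
  if (any(loci == ""))
    stop("GenePop parse error: empty locus name in header (line ",
         1L + which(trimws(header) == "")[1], ")")
  n_loci <- length(loci)

  inds <- character(0); pops <- character(0)
  a1 <- NULL; a2 <- NULL
  width <- NA_integer_
  blocks <- c(pop_idx, length(lines) + 1L)
  for (b in seq_along(pop_idx)) {
    rows <- lines[seq.int(blocks[b] + 1L, blocks[b + 1L] - 1L)]
    if (length(rows) == 0L)
      stop("GenePop parse error: empty POP block at line ", pop_idx[b])
    block_label <- NULL
    for (k in seq_along(rows)) {
      line_no <- blocks[b] + k
      parts <- strsplit(rows[k], ",")[[1]]
      if (length(parts) < 2L)
        stop("GenePop parse error: missing ',' separator at line ", line_no)
      name <- trimws(parts[1])
      calls <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[[:space:]]+")[[1]]
      if (length(calls) != n_loci)
        stop("GenePop parse error: expected ", n_loci, " genotypes, got ",
             length(calls), " at line ", line_no)
      w <- unique(nchar(calls))
      if (length(w) != 1L || !(w %in% c(4L, 6L)))
        stop("GenePop parse error: genotype codes must be uniformly 4 or 6 ",
             "digits at line ", line_no)
      half <- w %/% 2L
      if (is.na(width)) width <- half
      if (half != width)
        stop("GenePop parse error: inconsistent allele-code width (",
             half, " vs ", width, " digits) at line ", line_no)
      if (any(!grepl("^[0-9]+$", calls)))
        stop("GenePop parse error: non-numeric genotype at line ", line_no)
      v1 <- as.integer(substr(calls, 1L, half))
      v2 <- as.integer(substr(calls, half + 1L, w))
      v1[v1 == 0L] <- NA_integer_
      v2[v2 == 0L] <- NA_integer_
      # a single-missing allele cannot be represented; treat as missing pair
      miss <- is.na(v1) | is.na(v2)
      v1[miss] <- NA_integer_; v2[miss] <- NA_integer_
      if (is.null(block_label))
        block_label <- if (pop_labels == "first_individual") name else
          paste0("pop", b)
      inds <- c(inds, name); pops <- c(pops, block_label)
      a1 <- rbind(a1, v1); a2 <- rbind(a2, v2)
    }
  }
  genotype_table(inds, pops, loci, a1, a2)
}

#' Write a genotype table as a GenePop file
#'
#' @param table a [genotype_table()].
#' @param path output path.
#' @param digits allele-code width, 2 or 3.
#' @param title title line written at the top of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(table, path, digits = 3, title = "bridesnet export") {
  stopifnot(inherits(table, "genotype_table"), digits %in% c(2, 3))
  mx <- max(c(table$allele1, table$allele2), na.rm = TRUE)
  if (mx >= 10^digits)
    stop("allele code ", mx, " does not fit in ", digits, " digits")
  fmt <- function(m) {
    out <- sprintf(paste0("%0", digits, "d"), ifelse(is.na(m), 0L, m))
    matrix(out, nrow = nrow(m))
  }
  s1 <- fmt(table$allele1); s2 <- fmt(table$allele2)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(title, table$loci), con)
  for (p in unique(table$populations)) {
    writeLines("POP", con)
    for (i in which(table$populations == p)) {
      writeLines(paste0(table$individuals[i], " , ",
                        paste(paste0(s1[i, ], s2[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a population attribute table
#'
#' Reads a delimited file with (case-insensitive, order-free) columns
#' `Id`, `N`, `HE`, `PSize`, `EO`: population id, sample size, expected
#' heterozygosity, estimated population size, and element-occurrence
#' viability rank. Extra columns are carried through.
#'
#' @param path path to a CSV/TSV file with a header.
#' @param sep field separator (default `","`).
#' @return a data.frame with columns `Id`, `N`, `HE`, `PSize`, `EO` (EO as
#'   an ordered factor, best viability first) plus any extra columns.
#' @export
read_population_attributes <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  want <- c("Id", "N", "HE", "PSize", "EO")
  pos <- match(tolower(want), tolower(names(df)))
  if (anyNA(pos))
    stop("missing required column(s): ",
         paste(want[is.na(pos)], collapse = ", "))
  names(df)[pos] <- want
  if (anyDuplicated(df$Id))
    stop("duplicate population id: ",
         paste(unique(df$Id[duplicated(df$Id)]), collapse = ", "))
  df$EO <- validate_eo(df$EO)
  if (any(df$HE < 0 | df$HE > 1, na.rm = TRUE))
    stop("HE must lie in [0, 1]")
  if (any(df$N < 0 | df$N != round(df$N), na.rm = TRUE) ||
      any(df$PSize < 0 | df$PSize != round(df$PSize), na.rm = TRUE))
    stop("N and PSize must be non-negative integers")
  df[c(want, setdiff(names(df), want))]
}

#' Element-occurrence rank vocabulary
#'
#' EO viability ranks run from A (excellent) to D (poor), with composite
#' ranks for uncertain estimates; the order used throughout is
#' A > AB > B > BC > C > CD > D.
#' @return character vector of the seven tokens, best first.
#' @export
eo_levels <- function() c("A", "AB", "B", "BC", "C", "CD", "D")

validate_eo <- function(x) {
  x <- toupper(trimws(as.character(x)))
  bad <- setdiff(unique(x), eo_levels())
  if (length(bad))
    stop("unknown EO rank token(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(eo_levels(), collapse = ", "))
  factor(x, levels = eo_levels(), ordered = TRUE)
}

#' Numeric EO viability score (higher = better viability)
#' @param eo character vector or factor of EO tokens.
#' @return integer vector, 7 for A down to 1 for D.
#' @export
eo_score <- function(eo) {
  eo <- validate_eo(eo)
  length(eo_levels()) + 1L - as.integer(eo)
}

#' Expected heterozygosity per population
#'
#' For each population and locus, allele frequencies are computed from the
#' non-missing genotypes (n diploid individuals typed at the locus) and the
#' per-locus gene diversity is `(2n/(2n-1)) * (1 - sum(p^2))` — Nei's
#' unbiased estimator. A population's H_E is the mean over loci with at
#' least one typed individual. Populations with no typed genotype at any
#' locus get `NA`.
#'
#' @param table a [genotype_table()].
#' @param unbiased apply the small-sample `2n/(2n-1)` correction
#'   (default `TRUE`).
#' @return named numeric vector, one H_E in `[0, 1]` per population.
#' @export
expected_heterozygosity <- function(table, unbiased = TRUE) {
  stopifnot(inherits(table, "genotype_table"))
  pops <- unique(table$populations)
  out <- stats::setNames(rep(NA_real_, length(pops)), pops)
  for (p in pops) {
    rows <- table$populations == p
    hs <- vapply(seq_along(table$loci), function(j) {
      a <- c(table$allele1[rows, j], table$allele2[rows, j])
      a <- a[!is.na(a)]
      if (length(a) == 0L) return(NA_real_)
      n2 <- length(a)                       # 2n gene copies
      h <- 1 - sum((table(a) / n2)^2)
      if (unbiased && n2 > 1L) h <- h * n2 / (n2 - 1L)
      h
    }, numeric(1))
    if (any(!is.na(hs))) out[p] <- mean(hs, na.rm = TRUE)
  }
  out
}
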