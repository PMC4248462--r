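#' Pileup site
#'
#' One genomic site of a multi-individual pileup. Coordinates are 1-based and
#' inclusive throughout the package (the samtools pileup convention). Base
#' qualities are numeric phred scores (decoded from phred+33 ASCII on input).
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position (>= 1).
#' @param ref Reference base, one of A,C,G,T,N.
#' @param reads List with one element per individual; each element is a list
#'   with character vector `base` and integer vector `qual` of equal length.
#'   An individual with no reads is an empty `list(base = character(0),
#'   qual = integer(0))`, never omitted.
#' @param anc Optional ancestral base.
#' @return An object of class `pileup_site`.
#' @export
pileup_site <- function(chrom, pos, ref, reads, anc = NA_character_) {
  stopifnot(is.numeric(pos), pos >= 1)
  for (rd in reads) {
    if (length(rd$base) != length(rd$qual))
      stop("base and qual vectors differ in length")
    if (length(rd$base) && !all(rd$base %in% BASES))
      stop("invalid base in reads: ", paste(setdiff(rd$base, BASES), collapse = ","))
    if (length(rd$qual) && any(rd$qual < 0)) stop("negative base quality")
  }
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref, anc = anc, reads = reads),
            class = "pileup_site")
}

# Scan one mpileup bases column, returning the read-base tokens that pair
# one-to-one with the quality string. '^X' (start-of-read + mapQ char), '$'
# and '+n'/'-n' indel sequences consume no quality character and are dropped.
parse_base_tokens <- function(bstr) {
  if (!grepl("[\\^$+-]", bstr)) return(strsplit(bstr, "", fixed = TRUE)[[1]])
  chars <- strsplit(bstr, "", fixed = TRUE)[[1]]
  out <- character(length(chars))
  n_out <- 0L
  i <- 1L
  L <- length(chars)
  digits <- as.character(0:9)
  while (i <= L) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L                      # consume the mapping-quality character
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      num <- ""
      while (j <= L && chars[j] %in% digits) {
        num <- paste0(num, chars[j])
        j <- j + 1L
      }
      if (num == "") stop("malformed indel annotation in bases column")
      i <- j + as.integer(num)
    } else {
      n_out <- n_out + 1L
      out[n_out] <- ch
      i <- i + 1L
    }
  }
  out[seq_len(n_out)]
}

#' Read samtools-style text mpileup
#'
#' Parses a multi-individual text pileup (3 + 3 columns per individual:
#' depth, bases, phred+33 qualities). The bases-column grammar is handled in
#' full: `.`/`,` resolve to the reference base, `^X` consumes the following
#' mapping-quality character, `$` is consumed, `+n`/`-n` indel sequences are
#' skipped, `*` and `N` are dropped, and lower-case (reverse-strand) symbols
#' are uppercased. Bases with quality below `min_baseQ` are removed.
#'
#' Text pileups carry no per-read mapping quality, so `min_mapQ` is accepted
#' for interface compatibility but has no effect here.
#'
#' @param path File path or connection to mpileup text.
#' @param n_individuals Number of individuals expected per line.
#' @param min_baseQ Minimum phred base quality to keep a read (default 0).
#' @param min_mapQ Ignored for text pileups (see Details).
#' @return List of [pileup_site] objects in file order.
#' @export
read_mpileup <- function(path, n_individuals, min_baseQ = 0, min_mapQ = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  ncol_expect <- 3L + 3L * n_individuals
  for (li in seq_along(lines)) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    if (length(f) != ncol_expect)
      stop(sprintf("mpileup line %d: expected %d columns, found %d",
                   li, ncol_expect, length(f)))
    ref <- toupper(f[3])
    reads <- vector("list", n_individuals)
    for (ind in seq_len(n_individuals)) {
      depth <- suppressWarnings(as.integer(f[3L + 3L * ind - 2L]))
      if (is.na(depth))
        stop(sprintf("mpileup line %d: non-numeric depth for individual %d", li, ind))
      if (depth == 0L) {
        reads[[ind]] <- list(base = character(0), qual = integer(0))
        next
      }
      toks <- parse_base_tokens(f[3L + 3L * ind - 1L])
      if (length(toks) != depth)
        stop(sprintf(
          "mpileup line %d: individual %d declares depth %d but %d bases parsed",
          li, ind, depth, length(toks)))
      quals <- utf8ToInt(f[3L + 3L * ind]) - 33L
      if (length(quals) != depth)
        stop(sprintf("mpileup line %d: individual %d quality string length %d != depth %d",
                     li, ind, length(quals), depth))
      b <- toupper(toks)
      b[b %in% c(".", ",")] <- ref
      keep <- !(b %in% c("*", "N", ">", "<")) & quals >= min_baseQ
      b <- b[keep]
      quals <- quals[keep]
      if (length(b) && !all(b %in% BASES))
        stop(sprintf("mpileup line %d: unexpected base symbol '%s'",
                     li, setdiff(b, BASES)[1]))
      reads[[ind]] <- list(base = b, qual = as.integer(quals))
    }
    out[[li]] <- pileup_site(chrom = f[1], pos = as.integer(f[2]), ref = ref,
                             reads = reads)
  }
  out
}

#' Write sites as text mpileup
#'
#' Inverse of [read_mpileup] for simulator output: emits `.` for bases equal
#' to the reference and phred+33 quality characters.
#'
#' @param sites List of [pileup_site] objects.
#' @param path Output file path or connection.
#' @export
write_mpileup <- function(sites, path) {
  lines <- vapply(sites, function(s) {
    cols <- c(s$chrom, s$pos, s$ref)
    for (rd in s$reads) {
      d <- length(rd$base)
      if (d == 0L) {
        cols <- c(cols, "0", "*", "*")
      } else {
        b <- ifelse(rd$base == s$ref, ".", rd$base)
        q <- intToUtf8(pmin(rd$qual, 93L) + 33L, multiple = FALSE)
        cols <- c(cols, as.character(d), paste(b, collapse = ""), q)
      }
    }
    paste(cols, collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a BEAGLE genotype-probability file
#'
#' Whitespace-separated text with header
#' `marker allele1 allele2 Ind0 Ind0 Ind0 ...` and one genotype-probability
#' triple (major-hom, het, minor-hom) per individual per row. Each triple
#' must sum to 1 within 1e-6.
#'
#' @param path File path or connection.
#' @return List of records, each a list with `marker`, `allele1`, `allele2`
#'   and `gp`, an n x 3 probability matrix.
#' @export
read_beagle <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty BEAGLE file (missing header)")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 3L || (length(hdr) - 3L) %% 3L != 0L)
    stop("BEAGLE header must have 3 + 3*n_individuals columns")
  n_ind <- (length(hdr) - 3L) %/% 3L
  lapply(seq_along(lines[-1]), function(i) {
    f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(f) != 3L + 3L * n_ind)
      stop(sprintf("BEAGLE line %d: expected %d probability values, found %d",
                   i + 1L, 3L * n_ind, length(f) - 3L))
    p <- suppressWarnings(as.numeric(f[-(1:3)]))
    if (anyNA(p)) stop(sprintf("BEAGLE line %d: non-numeric probability", i + 1L))
    gp <- matrix(p, ncol = 3L, byrow = TRUE)
    if (any(p < -1e-9 | p > 1 + 1e-9)) stop(sprintf("BEAGLE line %d: probability outside [0,1]", i + 1L))
    if (any(abs(rowSums(gp) - 1) > 1e-6))
      stop(sprintf("BEAGLE line %d: genotype-probability triple does not sum to 1", i + 1L))
    list(marker = f[1], allele1 = f[2], allele2 = f[3], gp = gp)
  })
}

#' Write a BEAGLE genotype-probability file
#'
#' @param records List of records as returned by [read_beagle].
#' @param path Output file path or connection.
#' @export
write_beagle <- function(records, path) {
  n_ind <- if (length(records)) nrow(records[[1]]$gp) else 0L
  hdr <- c("marker", "allele1", "allele2",
           rep(paste0("Ind", seq_len(n_ind) - 1L), each = 3L))
  lines <- vapply(records, function(r) {
    paste(c(r$marker, r$allele1, r$allele2,
            sprintf("%.6f", as.vector(t(r$gp)))), collapse = "\t")
  }, character(1))
  writeLines(c(paste(hdr, collapse = "\t"), lines), path)
}

#' Sample-allele-frequency likelihood table
#'
#' Container for per-site SAF likelihood vectors: `logp[s, j+1]` is
#' log p(data at site s | j derived alleles in the sample), normalized so the
#' row maximum is 0 (per-site constants are irrelevant downstream).
#'
#' @param chrom,pos Site coordinates (1-based).
#' @param logp Numeric matrix, sites x (2n+1).
#' @param n_individuals Number of diploid individuals n.
#' @return An object of class `saf_table`.
#' @export
saf_table <- function(chrom, pos, logp, n_individuals) {
  logp <- as.matrix(logp)
  if (ncol(logp) != 2L * n_individuals + 1L)
    stop("logp must have 2*n_individuals + 1 columns")
  if (nrow(logp) != length(pos) || length(chrom) != length(pos))
    stop("chrom, pos and logp rows must agree")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 logp = unname(logp), n_individuals = as.integer(n_individuals)),
            class = "saf_table")
}

#' @rdname saf_table
#' @param x A `saf_table`.
#' @param ... Unused.
#' @export
print.saf_table <- function(x, ...) {
  cat(sprintf("saf_table: %d sites, %d diploid individuals (%d allele classes)\n",
              nrow(x$logp), x$n_individuals, ncol(x$logp)))
  invisible(x)
}

#' Write / read SAF likelihoods as TSV
#'
#' Plain-text persistence of a [saf_table] between pipeline stages: columns
#' `chrom`, `pos`, then `d0..d2n` log-likelihood values printed with 15
#' significant digits (round-trips to at least 12).
#'
#' @param saf A [saf_table].
#' @param path File path.
#' @export
write_saf <- function(saf, path) {
  K <- ncol(saf$logp)
  hdr <- paste(c("chrom", "pos", paste0("d", seq_len(K) - 1L)), collapse = "\t")
  body <- apply(saf$logp, 1L, function(r) paste(sprintf("%.15g", r), collapse = "\t"))
  if (nrow(saf$logp) == 0L) {
    writeLines(hdr, path)
  } else {
    writeLines(c(hdr, paste(saf$chrom, saf$pos, body, sep = "\t")), path)
  }
}

#' @rdname write_saf
#' @return `read_saf` returns a [saf_table].
#' @export
read_saf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty SAF file (missing header)")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  K <- length(hdr) - 2L
  if (K < 1L || (K - 1L) %% 2L != 0L)
    stop("SAF header must contain an odd number (2n+1) of value columns")
  body <- lines[-1]
  if (!length(body))
    return(saf_table(character(0), integer(0),
                     matrix(numeric(0), 0L, K), (K - 1L) %/% 2L))
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(f) != K + 2L)
  if (length(bad))
    stop(sprintf("SAF line %d: expected %d columns, found %d",
                 bad[1] + 1L, K + 2L, length(f[[bad[1]]])))
  m <- matrix(as.numeric(unlist(lapply(f, `[`, -(1:2)))), ncol = K, byrow = TRUE)
  saf_table(vapply(f, `[`, "", 1L), as.integer(vapply(f, `[`, "", 2L)),
            m, (K - 1L) %/% 2L)
}

#' Parse a region string
#'
#' `"chr1:100-200"` gives a 1-based inclusive region; a bare chromosome name
#' (`"chr1"`) means the whole chromosome (`start = 1`, `end = NA`).
#'
#' @param text Region string.
#' @return List with `chrom`, `start`, `end` (`end = NA` for whole chromosome).
#' @export
parse_region <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  if (!grepl(":", text, fixed = TRUE))
    return(list(chrom = text, start = 1L, end = NA_integer_))
  m <- regmatches(text, regexec("^([^:]+):([0-9]+)-([0-9]+)$", text))[[1]]
  if (length(m) != 4L) stop("malformed region string: ", text)
  start <- as.integer(m[3])
  end <- as.integer(m[4])
  if (start < 1L || start > end)
    stop("invalid region bounds (need 1 <= start <= end): ", text)
  list(chrom = m[2], start = start, end = end)
}

#' Look up ancestral bases for sites
#'
#' Accepts either a FASTA file (ancestral genome; looked up by chromosome
#' name and position) or a TSV with columns chrom, pos, base.
#'
#' @param path FASTA (.fa/.fasta) or TSV file.
#' @param chrom,pos Vectors of site coordinates (1-based).
#' @return Character vector of ancestral bases (NA where unknown / not ACGT).
#' @export
ancestral_bases <- function(path, chrom, pos) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fa", "fasta", "fna")) {
    seqs <- Biostrings::readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    out <- rep(NA_character_, length(pos))
    for (ch in unique(chrom)) {
      if (!ch %in% names(seqs)) next
      s <- as.character(seqs[[ch]])
      idx <- which(chrom == ch & pos <= nchar(s))
      if (!length(idx)) next
      out[idx] <- toupper(substring(s, pos[idx], pos[idx]))
    }
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             col.names = c("chrom", "pos", "base"),
                             colClasses = c("character", "integer", "character"))
    key <- paste(chrom, pos, sep = "_")
    out <- toupper(tab$base[match(key, paste(tab$chrom, tab$pos, sep = "_"))])
  }
  out[!out %in% BASES] <- NA_character_
  out
}
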