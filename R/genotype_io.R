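# Shared data model ----------------------------------------------------------
#
# A genotype panel is a plain list of two pieces:
#   geno : integer matrix, samples x markers, entries 0/1/2 counting copies of
#          the alternate allele, NA for missing. dimnames = (samples, markers).
#   map  : data.frame(marker, chrom, pos, ref, alt) sorted by (chrom, pos),
#          one row per column of geno, 1-based bp positions.
# Every function in the package takes and returns this pair; missingness is
# always NA, never 0.

IUPAC_HET <- c(AC = "M", CA = "M", AG = "R", GA = "R", AT = "W", TA = "W",
               CG = "S", GC = "S", CT = "Y", TC = "Y", GT = "K", TG = "K")

#' Assemble and validate a genotype panel
#'
#' Bundles a dosage matrix and a marker map into the panel structure used by
#' every analysis in the package, sorting markers by (chromosome, position)
#' and checking the invariants of the data model.
#'
#' @param geno integer matrix, samples x markers, entries in \{0, 1, 2, NA\}
#'   counting alternate-allele copies.
#' @param map data.frame with columns \code{marker}, \code{chrom}, \code{pos}
#'   and optionally \code{ref}, \code{alt}; one row per marker column.
#' @return list with elements \code{geno} and \code{map}, markers sorted by
#'   (chromosome, position).
#' @export
genotype_panel <- function(geno, map) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(colnames(geno))) colnames(geno) <- as.character(map$marker)
  if (is.null(rownames(geno))) rownames(geno) <- paste0("S", seq_len(nrow(geno)))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (!all(c("marker", "chrom", "pos") %in% names(map)))
    stop("map must have columns marker, chrom, pos")
  if (is.null(map$ref)) map$ref <- "A"
  if (is.null(map$alt)) map$alt <- "T"
  map <- map[, c("marker", "chrom", "pos", "ref", "alt")]
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (ncol(geno) != nrow(map)) stop("geno/map dimension mismatch")
  if (anyDuplicated(rownames(geno))) stop("duplicate sample IDs")
  if (anyDuplicated(map$marker)) stop("duplicate marker IDs")
  if (any(map$pos <= 0L)) stop("positions must be positive 1-based bp")
  if (anyDuplicated(map[, c("chrom", "pos")]))
    stop("duplicate (chromosome, position) pairs in map")
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  geno <- geno[, ord, drop = FALSE]
  colnames(geno) <- map$marker
  list(geno = geno, map = map)
}

#' Read a genotype matrix and marker map
#'
#' Reads diploid biallelic SNP genotypes into the shared panel structure.
#' Three dialects are supported: VCF 4.x (via \pkg{vcfR}), HapMap-style
#' tab-delimited text (\code{rs#, alleles, chrom, pos, ...} header followed by
#' sample columns holding either single IUPAC codes or two-letter allele
#' pairs, auto-detected), and a plain sample-by-marker matrix (CSV/TSV with a
#' sidecar map, see \code{\link{write_genotypes}}).
#'
#' Non-biallelic sites are skipped with a message reporting the count.
#' Heterozygous genotypes map to dosage 1 regardless of phasing.
#'
#' @param path file path (for \code{format = "matrix"}, the genotype file;
#'   the map is read from \code{paste0(path, ".map")}).
#' @param format one of \code{"vcf"}, \code{"hapmap"}, \code{"matrix"}.
#' @return a genotype panel (list with \code{geno}, \code{map}).
#' @export
read_genotypes <- function(path, format = c("vcf", "hapmap", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    vcf = read_genotypes_vcf(path),
    hapmap = read_genotypes_hapmap(path),
    matrix = read_genotypes_matrix(path))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  n_skip <- sum(!biallelic)
  if (n_skip > 0) {
    message("read_genotypes: skipped ", n_skip, " non-biallelic site(s)")
    v <- v[biallelic, ]
    fix <- fix[biallelic, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  ids <- fix$ID
  if (is.null(ids) || anyNA(ids) || any(ids == "."))
    ids <- paste0(fix$CHROM, "_", fix$POS)
  map <- data.frame(marker = ids, chrom = fix$CHROM,
                    pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  geno <- t(dos)
  rownames(geno) <- colnames(gt)
  colnames(geno) <- ids
  genotype_panel(geno, map)
}

read_genotypes_hapmap <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 12L || hdr[1] != "rs#")
    stop("not a HapMap file (expected 'rs#' header): ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  samples <- hdr[-(1:11)]
  alleles <- strsplit(tab$alleles, "/", fixed = TRUE)
  biallelic <- lengths(alleles) == 2L
  n_skip <- sum(!biallelic)
  if (n_skip > 0) {
    message("read_genotypes: skipped ", n_skip, " non-biallelic site(s)")
    tab <- tab[biallelic, , drop = FALSE]
    alleles <- alleles[biallelic]
  }
  ref <- vapply(alleles, `[`, "", 1L)
  alt <- vapply(alleles, `[`, "", 2L)
  calls <- as.matrix(tab[, samples, drop = FALSE])
  # sniff dialect: allele-pair cells are two characters wide
  pair_dialect <- any(nchar(calls[!is.na(calls) & calls != "NA"]) == 2L)
  dos <- matrix(NA_integer_, nrow(calls), ncol(calls))
  if (pair_dialect) {
    dos[calls == paste0(ref, ref)] <- 0L
    dos[calls == paste0(alt, alt)] <- 2L
    het <- calls == paste0(ref, alt) | calls == paste0(alt, ref)
    dos[het] <- 1L
  } else {
    dos[calls == ref] <- 0L
    dos[calls == alt] <- 2L
    het_code <- IUPAC_HET[paste0(ref, alt)]
    dos[calls == het_code] <- 1L
  }
  map <- data.frame(marker = tab[["rs#"]], chrom = tab$chrom,
                    pos = as.integer(tab$pos), ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  geno <- t(dos)
  rownames(geno) <- samples
  colnames(geno) <- map$marker
  genotype_panel(geno, map)
}

read_genotypes_matrix <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                           check.names = FALSE)
  map_path <- paste0(path, ".map")
  if (!file.exists(map_path)) stop("matrix format needs sidecar map: ", map_path)
  map <- utils::read.table(map_path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  geno <- as.matrix(tab)
  storage.mode(geno) <- "integer"
  genotype_panel(geno, map)
}

#' Write a genotype panel to disk
#'
#' Inverse of \code{\link{read_genotypes}}: the written file re-read under
#' the same format reproduces calls, sample/marker IDs and positions exactly
#' (including missing cells).
#'
#' @param panel genotype panel.
#' @param path output path (matrix format also writes \code{path.map}).
#' @param format one of \code{"vcf"}, \code{"hapmap"}, \code{"matrix"}.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(panel, path, format = c("vcf", "hapmap", "matrix")) {
  format <- match.arg(format)
  geno <- panel$geno; map <- panel$map
  switch(format,
    vcf = {
      gt <- matrix("./.", nrow(map), nrow(geno))
      tg <- t(geno)
      gt[tg == 0L] <- "0/0"; gt[tg == 1L] <- "0/1"; gt[tg == 2L] <- "1/1"
      body <- paste(map$chrom, map$pos, map$marker, map$ref, map$alt,
                    ".", "PASS", ".", "GT",
                    apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
      writeLines(c("##fileformat=VCFv4.2",
                   paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                          paste(rownames(geno), collapse = "\t")),
                   body), path)
    },
    hapmap = {
      calls <- matrix("NA", nrow(map), nrow(geno))
      tg <- t(geno)
      rr <- paste0(map$ref, map$ref); aa <- paste0(map$alt, map$alt)
      ra <- paste0(map$ref, map$alt)
      i0 <- which(tg == 0L); i1 <- which(tg == 1L); i2 <- which(tg == 2L)
      calls[i0] <- rr[row(calls)[i0]]
      calls[i1] <- ra[row(calls)[i1]]
      calls[i2] <- aa[row(calls)[i2]]
      hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                     "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                     rownames(geno)), collapse = "\t")
      body <- paste(map$marker, paste0(map$ref, "/", map$alt), map$chrom,
                    map$pos, "+", "NA", "NA", "NA", "NA", "NA", "NA",
                    apply(calls, 1L, paste, collapse = "\t"), sep = "\t")
      writeLines(c(hdr, body), path)
    },
    matrix = {
      sep <- if (grepl("\\.tsv$", path)) "\t" else ","
      utils::write.table(data.frame(sample = rownames(geno), geno,
                                    check.names = FALSE),
                         path, sep = sep, row.names = FALSE, quote = FALSE)
      utils::write.table(map, paste0(path, ".map"), sep = sep,
                         row.names = FALSE, quote = FALSE)
    })
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Imports \code{gene} features (other feature types are ignored) with
#' 1-based inclusive coordinates, the same convention as the marker map, so a
#' SNP at position p overlaps a gene [s, e] iff s <= p <= e.
#'
#' @param path GFF3 file.
#' @return data.frame with columns \code{gene}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{annotation}.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (length(genes) == 0L) {
    warning("no gene features found in ", path)
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), annotation = character()))
  }
  id <- genes$ID
  if (is.null(id)) id <- genes$Name
  if (is.null(id)) id <- paste0("gene", seq_along(genes))
  ann <- genes$Note
  if (is.null(ann)) ann <- genes$description
  if (is.null(ann)) ann <- rep(NA_character_, length(genes))
  ann <- vapply(ann, function(x) paste(unlist(x), collapse = "; "), "")
  df <- as.data.frame(genes)
  data.frame(gene = as.character(id),
             chrom = as.character(df$seqnames),
             start = as.integer(df$start),
             end = as.integer(df$end),
             strand = as.character(df$strand),
             annotation = ann,
             stringsAsFactors = FALSE)
}

#' Read a sample metadata table
#'
#' CSV with columns \code{sample}, \code{subspecies}, \code{market_type} and
#' optionally \code{botanical_variety}; unknowns are permitted and kept as
#' the literal string \code{"unknown"}.
#'
#' @param path CSV path.
#' @return data.frame, one row per sample.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "subspecies", "market_type") %in% names(tab)))
    stop("sample table needs columns sample, subspecies, market_type")
  if (anyDuplicated(tab$sample)) stop("duplicate sample IDs in sample table")
  tab
}

#' Read a long-format trait table
#'
#' CSV with columns \code{sample}, \code{trait}, \code{env}, \code{value};
#' one row per replicate measurement.
#'
#' @param path CSV path.
#' @return data.frame of replicate-level phenotype records.
#' @export
read_traits <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "trait", "env", "value") %in% names(tab)))
    stop("trait table needs columns sample, trait, env, value")
  if (!all(is.finite(tab$value))) stop("trait values must be finite")
  tab
}
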