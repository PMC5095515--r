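#' Read a BED file (0-based, half-open)
#'
#' @param path BED path; empty files give a 0-row data.frame
#' @return data.frame(scaffold, start, end)
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0)))
  }
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(bed[, 1:3], c("scaffold", "start", "end"))
}

#' Read a population map TSV
#'
#' Expects columns individual and population, with optional lat and lon.
#' @param path TSV path with header
#' @return data.frame
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("individual", "population") %in% names(pm)))
  pm
}

#' Load variants from a VCF into the internal variant matrix
#'
#' Reads a VCF 4.x, retains biallelic SNPs only, removes sites falling inside
#' the exclusion mask, and attaches the population map. Genotype codes count
#' the alternate allele (0/1/2, NA for missing); the ancestral allele is
#' taken from the `AA=` INFO tag when present and must equal REF or ALT.
#'
#' @param vcf_path VCF path
#' @param mask_bed optional BED path or data.frame(scaffold, start, end) in
#'   0-based half-open coordinates; masked sites are dropped
#' @param popmap population map: path or data.frame(individual, population)
#' @param exclude_scaffolds optional character vector of scaffolds to drop
#'   (e.g. sex-linked scaffolds)
#' @return object of class `variant_matrix` with fields scaffold, pos, ref,
#'   alt, aa, geno (sites x individuals), popmap, phased (logical matrix),
#'   and a `removed` attribute logging per-scaffold filter counts
#' @export
load_variants <- function(vcf_path, mask_bed = NULL, popmap,
                          exclude_scaffolds = NULL) {
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fx <- vcf@fix
  n0 <- nrow(fx)
  if (n0 == 0) stop("no records in VCF: ", vcf_path)

  indiv <- colnames(vcf@gt)[-1]
  missing_ind <- setdiff(indiv, popmap$individual)
  if (length(missing_ind)) {
    stop("individuals in VCF absent from population map: ",
         paste(missing_ind, collapse = ", "))
  }
  popmap <- popmap[match(indiv, popmap$individual), , drop = FALSE]

  scaffold <- fx[, "CHROM"]
  pos <- as.integer(fx[, "POS"])
  ref <- fx[, "REF"]
  alt <- fx[, "ALT"]

  bases <- c("A", "C", "G", "T")
  is_snp <- ref %in% bases & alt %in% bases  # multi-allelic ALT contains ','
  keep <- is_snp
  removed <- data.frame(scaffold = unique(scaffold))
  removed$non_biallelic_snp <- vapply(removed$scaffold, function(sc)
    sum(!is_snp & scaffold == sc), integer(1))

  if (!is.null(exclude_scaffolds)) keep <- keep & !(scaffold %in% exclude_scaffolds)

  if (!is.null(mask_bed)) {
    mask <- if (is.character(mask_bed)) read_bed(mask_bed) else mask_bed
    in_mask <- rep(FALSE, n0)
    if (nrow(mask)) {
      for (sc in unique(mask$scaffold)) {
        m <- mask[mask$scaffold == sc, , drop = FALSE]
        idx <- which(scaffold == sc)
        if (!length(idx)) next
        p0 <- pos[idx] - 1L  # 0-based site coordinate
        hit <- rep(FALSE, length(idx))
        for (j in seq_len(nrow(m))) {
          hit <- hit | (p0 >= m$start[j] & p0 < m$end[j])
        }
        in_mask[idx] <- hit
      }
    }
    removed$masked <- vapply(removed$scaffold, function(sc)
      sum(in_mask & keep & scaffold == sc), integer(1))
    keep <- keep & !in_mask
  }

  gt <- vcf@gt[keep, -1, drop = FALSE]
  scaffold <- scaffold[keep]; pos <- pos[keep]
  ref <- ref[keep]; alt <- alt[keep]

  # positions must be strictly increasing within scaffold
  ord <- order(match(scaffold, unique(scaffold)), pos)
  if (any(ord != seq_along(ord))) {
    gt <- gt[ord, , drop = FALSE]
    scaffold <- scaffold[ord]; pos <- pos[ord]
    ref <- ref[ord]; alt <- alt[ord]
  }
  dup <- unlist(tapply(pos, scaffold, duplicated))
  if (any(dup)) stop("duplicated positions within scaffold")

  aa <- vcfR::extract.info(vcf, "AA")[keep]
  if (!all(is.na(aa))) {
    bad_aa <- !is.na(aa) & aa != ref & aa != alt
    aa[bad_aa] <- NA_character_
  }

  geno <- parse_gt_codes(gt)
  phased <- grepl("|", substr(gt, 1, 3), fixed = TRUE) & !is.na(geno)

  vm <- structure(list(
    scaffold = scaffold, pos = pos, ref = ref, alt = alt, aa = aa,
    geno = geno, phased = phased, gt = gt,
    individuals = colnames(gt), popmap = popmap
  ), class = "variant_matrix")
  attr(vm, "removed") <- removed
  vm
}

#' @keywords internal
parse_gt_codes <- function(gt) {
  core <- sub(":.*$", "", gt)
  codes <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
             "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  g <- codes[core]
  # vcfR may surface fully missing calls as NA
  bad <- is.na(g) & !is.na(core) & !(core %in% c("./.", ".|.", "."))
  if (any(bad)) {
    stop("malformed genotype field: ", core[which(bad)[1]])
  }
  matrix(g, nrow(gt), ncol(gt), dimnames = dimnames(gt))
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: %d biallelic SNPs, %d individuals, %d populations\n",
              length(x$pos), ncol(x$geno), length(unique(x$popmap$population))))
  invisible(x)
}

#' Write a variant matrix back to VCF
#'
#' Inverse of [load_variants()]: round-tripping reproduces genotype codes
#' exactly.
#' @param vm variant_matrix
#' @param path output path
#' @export
write_variant_vcf <- function(vm, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=crowscape",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vm$individuals), collapse = "\t")
  )
  gt_chr <- matrix("./.", nrow(vm$geno), ncol(vm$geno))
  sep <- ifelse(vm$phased, "|", "/")
  a1 <- ifelse(vm$geno == 2L, "1", "0")
  a2 <- ifelse(vm$geno >= 1L, "1", "0")
  ok <- !is.na(vm$geno)
  gt_chr[ok] <- paste0(a1[ok], sep[ok], a2[ok])
  info <- ifelse(is.na(vm$aa), ".", paste0("AA=", vm$aa))
  gt_glued <- do.call(paste, c(asplit(gt_chr, 2), list(sep = "\t")))
  body <- paste(vm$scaffold, vm$pos, ".", vm$ref, vm$alt, ".", "PASS",
                info, "GT", gt_glued, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Pair-specific site coverage filter
#'
#' Retains sites where each of the two populations has genotype calls for at
#' least 50% of its individuals (inclusive at exactly 50%).
#'
#' @param vm variant_matrix
#' @param popA,popB population labels
#' @param min_fraction minimum fraction of genotyped individuals per population
#' @return logical vector over sites
#' @export
site_coverage_filter <- function(vm, popA, popB, min_fraction = 0.5) {
  for (p in c(popA, popB)) {
    if (!p %in% vm$popmap$population) stop("population not present: ", p)
  }
  called_frac <- function(p) {
    cols <- which(vm$popmap$population == p)
    if (!length(cols)) stop("empty population: ", p)
    rowMeans(!is.na(vm$geno[, cols, drop = FALSE]))
  }
  called_frac(popA) >= min_fraction & called_frac(popB) >= min_fraction
}

#' Assign sites to non-overlapping windows
#'
#' Windows tile each scaffold in 0-based half-open coordinates; a site at
#' 1-based position P maps to window floor((P - 1) / window_size). Trailing
#' short windows (when scaffold lengths are supplied) are retained and
#' flagged; callable-site totals per window subtract exclusion-mask overlap
#' so that statistics normalized per available site (D_xy) use the actual
#' accessible span.
#'
#' @param vm variant_matrix
#' @param window_size window size in bases
#' @param mask optional mask data.frame(scaffold, start, end), 0-based
#'   half-open, used for the callable-site totals
#' @param scaffold_lengths optional named vector; defaults to the largest
#'   observed position per scaffold rounded up to a whole window
#' @return object of class `window_index`: list(windows = data.frame(scaffold,
#'   win, start, end, n_callable, short), site_window = integer vector mapping
#'   each site of `vm` to a row of `windows`)
#' @export
assign_windows <- function(vm, window_size, mask = NULL,
                           scaffold_lengths = NULL) {
  stopifnot(window_size > 0)
  scafs <- unique(vm$scaffold)
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- vapply(scafs, function(sc)
      ceiling(max(vm$pos[vm$scaffold == sc]) / window_size) * window_size,
      numeric(1))
  }
  win_rows <- lapply(scafs, function(sc) {
    len <- scaffold_lengths[[sc]]
    n_win <- ceiling(len / window_size)
    start <- (seq_len(n_win) - 1) * window_size
    end <- pmin(start + window_size, len)
    data.frame(scaffold = sc, win = seq_len(n_win) - 1L,
               start = start, end = end, short = end - start < window_size)
  })
  windows <- do.call(rbind, win_rows)
  windows$row <- seq_len(nrow(windows))

  # callable sites: window span minus mask overlap
  windows$n_callable <- windows$end - windows$start
  if (!is.null(mask) && nrow(mask)) {
    for (j in seq_len(nrow(mask))) {
      hit <- windows$scaffold == mask$scaffold[j]
      ov <- pmax(0, pmin(windows$end[hit], mask$end[j]) -
                    pmax(windows$start[hit], mask$start[j]))
      windows$n_callable[hit] <- windows$n_callable[hit] - ov
    }
    windows$n_callable <- pmax(windows$n_callable, 0)
  }

  key <- paste(windows$scaffold, windows$win)
  site_key <- paste(vm$scaffold, (vm$pos - 1L) %/% as.integer(window_size))
  site_window <- match(site_key, key)
  if (anyNA(site_window)) stop("site outside supplied scaffold lengths")
  structure(list(windows = windows, site_window = site_window,
                 window_size = window_size),
            class = "window_index")
}

#' Build a variant matrix directly from a simulated dataset
#'
#' Constructs the same object [load_variants()] would return from the
#' written VCF, without the disk round trip. The exclusion mask is applied.
#'
#' @param sim crow_sim
#' @param apply_mask drop sites in masked windows (default TRUE)
#' @return variant_matrix with genotype codes counting the DERIVED allele as
#'   alternate (ref = ancestral base)
#' @export
sim_variant_matrix <- function(sim, apply_mask = TRUE) {
  keep <- rep(TRUE, nrow(sim$sites))
  if (apply_mask && length(sim$truth$mask_windows)) {
    keep <- !(sim$sites$window %in% sim$truth$mask_windows)
  }
  geno <- sim$geno[keep, , drop = FALSE]
  phased_pop <- sim$popmap$population %in% names(sim$haplotypes)
  structure(list(
    scaffold = sim$sites$scaffold[keep],
    pos = sim$sites$pos[keep],
    ref = sim$anc_base[keep],
    alt = sim$der_base[keep],
    aa = sim$anc_base[keep],
    geno = geno,
    phased = matrix(rep(phased_pop, each = sum(keep)), nrow = sum(keep)),
    individuals = colnames(sim$geno),
    popmap = sim$popmap
  ), class = "variant_matrix")
}

#' Phased haplotype set for one population
#'
#' Returns per-scaffold matrices of 0 (ancestral) / 1 (derived) alleles for
#' the phased haplotypes of one population, either from a simulated dataset
#' or from a phased variant matrix.
#'
#' @param x crow_sim or variant_matrix
#' @param population population label
#' @param apply_mask for crow_sim input, drop masked windows
#' @return list of `hap_set` objects (one per scaffold): list(scaffold, pos,
#'   haps = sites x haplotypes 0/1 matrix, freq = derived-allele frequency)
#' @export
haplotype_set <- function(x, population, apply_mask = TRUE) {
  if (inherits(x, "crow_sim")) {
    hp <- x$haplotypes[[population]]
    if (is.null(hp)) stop("no haplotypes emitted for population ", population)
    keep <- rep(TRUE, nrow(x$sites))
    if (apply_mask && length(x$truth$mask_windows)) {
      keep <- !(x$sites$window %in% x$truth$mask_windows)
    }
    sites <- x$sites[keep, , drop = FALSE]
    hp <- hp[keep, , drop = FALSE]
    return(lapply(unique(sites$scaffold), function(sc) {
      idx <- sites$scaffold == sc
      h <- hp[idx, , drop = FALSE]
      structure(list(scaffold = sc, pos = sites$pos[idx], haps = h,
                     freq = rowMeans(h)), class = "hap_set")
    }))
  }
  if (inherits(x, "variant_matrix")) {
    cols <- which(x$popmap$population == population)
    if (!length(cols)) stop("population not present: ", population)
    ph <- x$phased[, cols, drop = FALSE]
    gt <- x$gt[, cols, drop = FALSE]
    if (is.null(gt)) stop("variant matrix lacks raw genotype strings")
    if (!all(ph | is.na(x$geno[, cols]))) {
      stop("unphased genotypes for population ", population,
           "; haplotype statistics need phased input")
    }
    if (anyNA(x$aa) && any(is.na(x$aa))) {
      keep_site <- !is.na(x$aa)
    } else keep_site <- rep(TRUE, length(x$pos))
    core <- sub(":.*$", "", gt)
    a1 <- matrix(as.integer(substr(core, 1, 1)), nrow(gt))
    a2 <- matrix(as.integer(substr(core, 3, 3)), nrow(gt))
    # interleave so the two haplotypes of an individual are adjacent
    ord <- as.vector(rbind(seq_along(cols), seq_along(cols) + length(cols)))
    hp_alt <- cbind(a1, a2)[, ord, drop = FALSE]
    # recode alt-dosage to derived coding using the ancestral allele
    der_is_alt <- x$aa == x$ref
    hp <- hp_alt
    hp[!der_is_alt, ] <- 1L - hp[!der_is_alt, , drop = FALSE]
    hp <- hp[keep_site, , drop = FALSE]
    scaffold <- x$scaffold[keep_site]
    pos <- x$pos[keep_site]
    return(lapply(unique(scaffold), function(sc) {
      idx <- scaffold == sc
      h <- hp[idx, , drop = FALSE]
      structure(list(scaffold = sc, pos = pos[idx], haps = h,
                     freq = rowMeans(h)), class = "hap_set")
    }))
  }
  stop("unsupported input")
}

#' Derived-allele counts for one population
#'
#' @param vm variant_matrix
#' @param population label
#' @return list(derived = per-site derived-allele count (NA where the
#'   ancestral state is missing), called = called allele count,
#'   alt = alternate-allele count)
#' @export
pop_allele_counts <- function(vm, population) {
  cols <- which(vm$popmap$population == population)
  if (!length(cols)) stop("population not present: ", population)
  g <- vm$geno[, cols, drop = FALSE]
  called <- 2L * rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  der <- rep(NA_real_, length(alt))
  known <- !is.na(vm$aa)
  der[known & vm$aa == vm$ref] <- alt[known & vm$aa == vm$ref]
  der[known & vm$aa == vm$alt] <- (called - alt)[known & vm$aa == vm$alt]
  list(derived = der, called = called, alt = alt)
}
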