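## Seeded synthetic data generator. Emits toy genomes, annotations, small RNA
## loci with read stacks, count matrices and degradome profiles with planted
## ground truth, so that every downstream stage of the pipeline can be tested
## without sequencing data. Each operation draws from its own pseudo-random
## stream, seeded from the configuration seed plus a fixed per-operation
## offset, so partial re-runs are reproducible.

.seed_offset <- c(annotation = 101L, srna = 211L, counts = 307L,
                  degradome = 401L, lncrna = 503L)

#' Configuration for the synthetic data generator
#'
#' The defaults define the study conditions emulated throughout the test
#' suite: five dormancy/flowering stages (T1/T2/T3 = 0/500/1000 chill hours,
#' D3/D7 = days 3/7 of warmth) with 3 replicates each except T3, which has 2
#' (one replicate of the real experiment was discarded as an outlier).
#'
#' @param seed Integer seed for all generator streams.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes,n_repeats,n_qtl Numbers of gene models, repeat intervals
#'   and QTL regions.
#' @param n_srna_loci Number of small RNA loci (>= 40).
#' @param n_lncrna Number of lncRNA candidate transcripts.
#' @param n_mirna Number of mature microRNA sequences.
#' @param stage_names Ordered, distinct stage labels.
#' @param replicates_per_stage Integer vector, same length as `stage_names`.
#' @param nb_dispersion Negative binomial dispersion (> 0) for counts.
#' @param planted_fc Fold change (>= 1) planted into differentially
#'   expressed features.
#' @param planted_de_fraction Fraction in `[0, 1]` of features planted as
#'   differentially expressed.
#' @param phase_length Phasing register length in nt (>= 2; 24 for the
#'   miR2275-triggered phasiRNA pathway).
#' @param phas_noise_fraction Fraction in `[0, 1]` of off-register reads at
#'   the planted PHAS locus.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 2L,
                             chrom_length = 1e6,
                             n_genes = 60L,
                             n_repeats = 80L,
                             n_qtl = 2L,
                             n_srna_loci = 500L,
                             n_lncrna = 60L,
                             n_mirna = 30L,
                             stage_names = STAGE_NAMES,
                             replicates_per_stage = c(3L, 3L, 2L, 3L, 3L),
                             nb_dispersion = 0.05,
                             planted_fc = 4,
                             planted_de_fraction = 0.1,
                             phase_length = 24L,
                             phas_noise_fraction = 0.05) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), n_repeats = as.integer(n_repeats),
              n_qtl = as.integer(n_qtl), n_srna_loci = as.integer(n_srna_loci),
              n_lncrna = as.integer(n_lncrna), n_mirna = as.integer(n_mirna),
              stage_names = as.character(stage_names),
              replicates_per_stage = as.integer(replicates_per_stage),
              nb_dispersion = nb_dispersion, planted_fc = planted_fc,
              planted_de_fraction = planted_de_fraction,
              phase_length = as.integer(phase_length),
              phas_noise_fraction = phas_noise_fraction)
  counts <- c(cfg$n_chroms, cfg$chrom_length, cfg$n_genes, cfg$n_repeats,
              cfg$n_qtl, cfg$n_srna_loci, cfg$n_lncrna, cfg$n_mirna)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("synthetic_config: all counts must be >= 0")
  }
  if (anyDuplicated(cfg$stage_names)) {
    stop("synthetic_config: stage names must be distinct")
  }
  if (length(cfg$replicates_per_stage) != length(cfg$stage_names)) {
    stop("synthetic_config: replicates_per_stage must match stage_names")
  }
  if (cfg$nb_dispersion <= 0) stop("synthetic_config: nb_dispersion must be > 0")
  if (cfg$planted_fc < 1) stop("synthetic_config: planted_fc must be >= 1")
  if (cfg$planted_de_fraction < 0 || cfg$planted_de_fraction > 1) {
    stop("synthetic_config: planted_de_fraction must be in [0, 1]")
  }
  if (cfg$phase_length < 2L) stop("synthetic_config: phase_length must be >= 2")
  if (cfg$phas_noise_fraction < 0 || cfg$phas_noise_fraction > 1) {
    stop("synthetic_config: phas_noise_fraction must be in [0, 1]")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width[min(i, length(width))],
                 replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a toy genome annotation
#'
#' Places non-overlapping gene bodies (each with 1-3 exons), repeat
#' intervals that may overlap genes, QTL regions, reference sequence sets
#' for the known small RNA classes, and mature microRNA sequences.
#' Deterministic for a fixed configuration seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `chroms`, `genes`, `exons`, `repeats`, `qtl`
#'   (data frames, 0-based half-open), `class_refs` (list of named sequence
#'   vectors per class) and `mirnas` (named character vector; the first
#'   entry, `miR_001`, is reserved as the 22-nt phasiRNA trigger).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + .seed_offset[["annotation"]])
  chroms <- data.frame(chrom = paste0("Chr", seq_len(config$n_chroms)),
                       length = config$chrom_length,
                       stringsAsFactors = FALSE)

  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = character(0), exon_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (config$n_genes > 0) {
    chrom_of <- rep(chroms$chrom, length.out = config$n_genes)
    per_chrom <- table(factor(chrom_of, levels = chroms$chrom))
    slot <- config$chrom_length %/% max(per_chrom)
    if (slot < 3000L) {
      stop("generate_annotation: chromosomes too short to place ",
           config$n_genes, " non-overlapping genes")
    }
    rows <- lapply(seq_len(config$n_genes), function(i) {
      chr <- chrom_of[i]
      idx <- sum(chrom_of[seq_len(i)] == chr) - 1L
      len <- sample(2000:min(8000L, slot - 500L), 1)
      start <- idx * slot + sample.int(slot - len, 1) - 1L
      data.frame(gene_id = sprintf("gene_%03d", i), chrom = chr,
                 start = start, end = start + len,
                 strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    })
    genes <- do.call(rbind, rows)
    exon_rows <- lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      n_ex <- sample(1:3, 1)
      n_seg <- 2L * n_ex - 1L
      u <- runif(n_seg) + 0.3
      w <- floor((g$end - g$start) * u / sum(u))
      w[n_seg] <- (g$end - g$start) - sum(w[-n_seg])
      bounds <- g$start + c(0L, cumsum(w))
      ex <- seq(1L, n_seg, by = 2L)
      data.frame(gene_id = g$gene_id,
                 exon_id = sprintf("%s.exon%d", g$gene_id, seq_len(n_ex)),
                 chrom = g$chrom, start = bounds[ex], end = bounds[ex + 1L],
                 strand = g$strand, stringsAsFactors = FALSE)
    })
    exons <- do.call(rbind, exon_rows)
  }

  place <- function(n, prefix, width_range) {
    if (n == 0) {
      return(data.frame(name = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE))
    }
    w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
    if (any(w >= config$chrom_length)) {
      stop("generate_annotation: chromosome too short for requested features")
    }
    chr <- sample(chroms$chrom, n, replace = TRUE)
    start <- vapply(w, function(wi) sample.int(config$chrom_length - wi, 1) - 1L,
                    integer(1))
    data.frame(name = sprintf("%s_%03d", prefix, seq_len(n)), chrom = chr,
               start = start, end = start + w, strand = ".",
               stringsAsFactors = FALSE)
  }
  repeats <- place(config$n_repeats, "repeat", c(300L, 2000L))
  qtl <- place(config$n_qtl, "qtl", c(config$chrom_length %/% 12L,
                                      config$chrom_length %/% 10L))
  if (config$n_qtl > 0) {
    kind <- rep(c("qCR", "qBD"), length.out = config$n_qtl)
    qtl$name <- sprintf("%s%d", kind, seq_len(config$n_qtl))
  }

  ref_width <- c(rRNA = 150L, tRNA = 90L, snRNA = 120L, miRNA = 140L,
                 `ta-siRNA` = 120L)
  class_refs <- lapply(REFERENCE_CLASSES, function(cl) {
    s <- random_dna(2L, rep(ref_width[[cl]], 2L))
    names(s) <- sprintf("%s_ref_%d", sub("-", "_", cl), 1:2)
    s
  })
  names(class_refs) <- REFERENCE_CLASSES

  mir_w <- c(22L, sample(20:22, max(config$n_mirna - 1L, 0L), replace = TRUE))
  mirnas <- random_dna(config$n_mirna, mir_w[seq_len(config$n_mirna)])
  names(mirnas) <- sprintf("miR_%03d", seq_len(config$n_mirna))

  list(chroms = chroms, genes = genes, exons = exons, repeats = repeats,
       qtl = qtl, class_refs = class_refs, mirnas = mirnas)
}

## Definitional origin of an interval: repeat > gene > intergenic, >= 1 bp
## strand-agnostic overlap. Used by the generator to record ground truth.
truth_origin <- function(loci, genes, repeats) {
  origin <- rep("intergenic", nrow(loci))
  origin[overlaps_any0(loci, genes)] <- "gene"
  origin[overlaps_any0(loci, repeats)] <- "repeat"
  origin
}

#' Generate small RNA loci with planted class labels and a PHAS read stack
#'
#' Plants, at the configured locus count: loci whose major RNA is an exact
#' substring of a class reference (rRNA/tRNA/snRNA/miRNA/ta-siRNA),
#' repeat-resident 23-24 nt siRNA loci satisfying all three heterochromatic
#' siRNA criteria, plain siRNA loci (20-24 nt major RNA), loci with major
#' RNA outside 20-24 nt, and exactly one 24-nt PHAS locus carrying a phased
#' read stack (a fraction `1 - phas_noise_fraction` of read 5' starts in one
#' phasing register; minus-strand phased reads planted at register - 2 nt to
#' honour the 2-nt 3' overhang convention) plus a site complementary to the
#' trigger microRNA `miR_001` in its sequence.
#'
#' @param config A [synthetic_config()].
#' @param annotation Output of [generate_annotation()].
#' @return List with `loci` (data frame: `id`, `chrom`, `start`, `end`,
#'   `strand`, `major_rna_seq`, `major_rna_len`), `alignments` (data frame:
#'   `locus_id`, `chrom`, `start`, `end`, `strand`, `count`), `locus_seqs`
#'   (named character vector) and `truth` (list with per-locus `class` and
#'   `origin`, `hc_sirna_ids`, `phas_locus_id`, `phas_register`,
#'   `trigger_mirna`).
#' @export
generate_srna_loci <- function(config, annotation) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$phase_length < 2L) stop("phase_length must be >= 2")
  if (config$n_srna_loci < 40L) {
    stop("generate_srna_loci: need at least 40 loci to plant all classes")
  }
  set.seed(config$seed + .seed_offset[["srna"]])
  n <- config$n_srna_loci
  p <- config$phase_length
  n_per_class <- max(1L, n %/% 100L)
  n_hc <- floor(0.3 * n)
  n_other <- floor(0.15 * n)
  n_plain <- n - 5L * n_per_class - n_hc - n_other - 1L

  rand_interval <- function(width) {
    chr <- sample(annotation$chroms$chrom, 1)
    start <- sample.int(config$chrom_length - width, 1) - 1L
    list(chrom = chr, start = start, end = start + width)
  }

  rows <- list()
  seqs <- character(0)
  add <- function(chrom, start, end, major_seq) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end,
      strand = sample(c("+", "-"), 1), major_rna_seq = major_seq,
      major_rna_len = nchar(major_seq), stringsAsFactors = FALSE)
  }

  class_truth <- character(0)
  for (cl in REFERENCE_CLASSES) {
    refs <- annotation$class_refs[[cl]]
    for (i in seq_len(n_per_class)) {
      len <- sample(20:24, 1)
      ref <- refs[[sample.int(length(refs), 1)]]
      off <- sample.int(nchar(ref) - len + 1L, 1)
      iv <- rand_interval(sample(100:300, 1))
      add(iv$chrom, iv$start, iv$end, substr(ref, off, off + len - 1L))
      class_truth <- c(class_truth, cl)
    }
  }

  wide_repeats <- annotation$repeats[
    annotation$repeats$end - annotation$repeats$start >= 150L, , drop = FALSE]
  if (nrow(wide_repeats) == 0 && n_hc > 0) {
    stop("generate_srna_loci: no repeat wide enough to host hc-siRNA loci")
  }
  for (i in seq_len(n_hc)) {
    rp <- wide_repeats[sample.int(nrow(wide_repeats), 1), ]
    w <- min(sample(100:400, 1), rp$end - rp$start)
    start <- rp$start + sample.int(rp$end - rp$start - w + 1L, 1) - 1L
    add(rp$chrom, start, start + w, random_dna(1, sample(23:24, 1)))
    class_truth <- c(class_truth, "siRNA")
  }

  for (i in seq_len(n_plain)) {
    iv <- rand_interval(sample(100:400, 1))
    len <- sample(20:24, 1, prob = c(0.02, 0.06, 0.04, 0.03, 0.85))
    add(iv$chrom, iv$start, iv$end, random_dna(1, len))
    class_truth <- c(class_truth, "siRNA")
  }

  for (i in seq_len(n_other)) {
    iv <- rand_interval(sample(100:300, 1))
    len <- sample(c(18L, 19L, 25:30), 1)
    add(iv$chrom, iv$start, iv$end, random_dna(1, len))
    class_truth <- c(class_truth, "other")
  }

  ## One PHAS locus, 10 phasing cycles wide, kept clear of genes and repeats.
  phas_width <- 10L * p
  for (try in 1:200) {
    iv <- rand_interval(phas_width)
    probe <- data.frame(chrom = iv$chrom, start = iv$start, end = iv$end)
    if (!overlaps_any0(probe, annotation$genes) &&
        !overlaps_any0(probe, annotation$repeats)) break
    if (try == 200) stop("generate_srna_loci: could not place PHAS locus")
  }
  add(iv$chrom, iv$start, iv$end, random_dna(1, 24L))
  class_truth <- c(class_truth, "siRNA")

  loci <- do.call(rbind, rows)
  ord <- sample.int(nrow(loci))
  loci <- loci[ord, ]
  class_truth <- class_truth[ord]
  loci$id <- sprintf("locus_%05d", seq_len(nrow(loci)))
  loci <- loci[, c("id", "chrom", "start", "end", "strand",
                   "major_rna_seq", "major_rna_len")]
  rownames(loci) <- NULL
  phas_id <- loci$id[which(ord == length(rows))]

  origin <- truth_origin(loci, annotation$genes, annotation$repeats)
  hc_ids <- loci$id[origin == "repeat" & class_truth == "siRNA" &
                      loci$major_rna_len %in% c(23L, 24L)]

  ## Phased read stack at the PHAS locus.
  phas <- loci[loci$id == phas_id, ]
  reg <- sample.int(p, 1) - 1L
  total_reads <- 200L
  n_in <- if (config$phas_noise_fraction == 0) total_reads else
    rbinom(1, total_reads, 1 - config$phas_noise_fraction)
  cycles <- rep(0:9, length.out = n_in)
  minus <- cycles >= 1L & (seq_len(n_in) %% 3L == 0L)
  aln <- data.frame(
    locus_id = phas_id, chrom = phas$chrom,
    start = ifelse(minus, phas$start + reg + cycles * p - 25L,
                   phas$start + reg + cycles * p),
    end = ifelse(minus, phas$start + reg + cycles * p - 1L,
                 phas$start + reg + cycles * p + 24L),
    strand = ifelse(minus, "-", "+"), count = 1L,
    stringsAsFactors = FALSE)
  n_noise <- total_reads - n_in
  if (n_noise > 0) {
    off_register <- setdiff(0:(phas_width - 1L), seq(reg, phas_width - 1L, by = p))
    noise_start <- phas$start + sample(off_register, n_noise, replace = TRUE)
    aln <- rbind(aln, data.frame(
      locus_id = phas_id, chrom = phas$chrom, start = noise_start,
      end = noise_start + 24L, strand = "+", count = 1L,
      stringsAsFactors = FALSE))
  }
  ## Background read stacks at a few plain siRNA loci (uniform positions).
  bg_ids <- setdiff(loci$id[class_truth == "siRNA"], phas_id)
  bg_ids <- sample(bg_ids, min(10L, length(bg_ids)))
  for (id in bg_ids) {
    lc <- loci[loci$id == id, ]
    w <- lc$end - lc$start
    st <- lc$start + sample.int(max(w - 24L, 1L), 50L, replace = TRUE) - 1L
    aln <- rbind(aln, data.frame(
      locus_id = id, chrom = lc$chrom, start = st, end = st + 24L,
      strand = "+", count = 1L, stringsAsFactors = FALSE))
  }

  ## Locus sequences; the PHAS locus carries a site complementary to the
  ## trigger microRNA.
  widths <- loci$end - loci$start
  locus_seqs <- random_dna(nrow(loci), widths)
  names(locus_seqs) <- loci$id
  trigger <- annotation$mirnas[["miR_001"]]
  site <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(trigger)))
  ins <- sample.int(nchar(locus_seqs[[phas_id]]) - nchar(site) + 1L, 1)
  s <- locus_seqs[[phas_id]]
  locus_seqs[[phas_id]] <- paste0(substr(s, 1, ins - 1L), site,
                                  substr(s, ins + nchar(site), nchar(s)))

  truth <- list(class = setNames(class_truth, loci$id),
                origin = setNames(origin, loci$id),
                hc_sirna_ids = hc_ids,
                phas_locus_id = phas_id,
                phas_register = reg,
                trigger_mirna = "miR_001")
  list(loci = loci, alignments = aln, locus_seqs = locus_seqs, truth = truth)
}

## Definitional lncRNA taxonomy used by the generator to record ground
## truth: an independent quadratic scan over all genes, separate from the
## classifier implementation.
.lnc_truth_row <- function(chrom, start, end, strand, genes, exons) {
  cand <- which(genes$chrom == chrom)
  if (length(cand) == 0) return(NULL)
  gap <- pmax(0, pmax(start, genes$start[cand]) - pmin(end, genes$end[cand]))
  ov <- genes$start[cand] < end & genes$end[cand] > start
  ord <- order(gap, !ov, genes$gene_id[cand])
  g <- genes[cand[ord][1], ]
  direction <- if (strand == g$strand) "sense" else "antisense"
  if (g$start < end && g$end > start) {
    ge <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    hit <- any(ge$start < end & ge$end > start)
    list(direction = direction, zone = "genic",
         position = if (hit) "exonic" else "intronic", closest = g$gene_id)
  } else {
    before <- end <= g$start
    five <- if (g$strand == "-") !before else before
    list(direction = direction, zone = "intergenic",
         position = if (five) "upstream" else "downstream", closest = g$gene_id)
  }
}

#' Generate lncRNA candidate transcripts with planted taxonomy
#'
#' Places single-exon candidate transcripts around the annotated genes so
#' that all non-(sense-exonic) taxonomy cells are populated: inside introns,
#' across exons on the opposite strand, and up/downstream of genes. Each
#' transcript gets a random sequence of its width (random sequences
#' essentially never carry a 100-codon ORF, so candidates pass the coding
#' filter). The recorded truth is the definitional taxonomy of the realized
#' placement, computed by an independent scan.
#'
#' @param config A [synthetic_config()].
#' @param annotation Output of [generate_annotation()].
#' @return List with `transcripts` (data frame `id`, `chrom`, `start`,
#'   `end`, `strand`), `seqs` (named character vector) and `truth` (data
#'   frame `id`, `direction`, `zone`, `position`, `closest_gene`).
#' @export
generate_lncrna_candidates <- function(config, annotation) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + .seed_offset[["lncrna"]])
  genes <- annotation$genes
  exons <- annotation$exons
  if (nrow(genes) == 0) stop("generate_lncrna_candidates: no genes annotated")
  n <- config$n_lncrna
  kinds <- rep(c("intronic", "exonic_anti", "upstream", "downstream"),
               length.out = n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- NULL
    for (try in 1:80) {
      g <- genes[sample.int(nrow(genes), 1), ]
      ge <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
      ge <- ge[order(ge$start), , drop = FALSE]
      w <- sample(250:600, 1)
      kind <- kinds[i]
      if (kind == "intronic") {
        if (nrow(ge) < 2) next
        j <- sample.int(nrow(ge) - 1L, 1)
        lo <- ge$end[j]; hi <- ge$start[j + 1L]
        if (hi - lo < w + 2L) next
        start <- lo + sample.int(hi - lo - w, 1)
        strand <- sample(c(g$strand, setdiff(c("+", "-"), g$strand)), 1,
                         prob = c(0.5, 0.5))
      } else if (kind == "exonic_anti") {
        j <- sample.int(nrow(ge), 1)
        start <- max(0L, ge$start[j] - sample.int(100L, 1))
        strand <- setdiff(c("+", "-"), g$strand)
      } else {
        gap <- sample(500:20000, 1)
        if ((kind == "upstream") == (g$strand != "-")) {
          start <- g$start - gap - w
        } else {
          start <- g$end + gap
        }
        if (start < 0 || start + w > config$chrom_length) next
        strand <- sample(c("+", "-"), 1)
      }
      probe <- data.frame(chrom = g$chrom, start = start, end = start + w)
      if (kind %in% c("upstream", "downstream") &&
          any(genes$chrom == g$chrom & genes$start < probe$end &
                genes$end > probe$start)) {
        next
      }
      placed <- data.frame(id = sprintf("lnc_%04d", i), chrom = g$chrom,
                           start = as.integer(start),
                           end = as.integer(start + w), strand = strand,
                           stringsAsFactors = FALSE)
      break
    }
    if (is.null(placed)) {
      stop("generate_lncrna_candidates: could not place transcript ", i)
    }
    rows[[i]] <- placed
  }
  transcripts <- do.call(rbind, rows)
  seqs <- setNames(random_dna(n, transcripts$end - transcripts$start),
                   transcripts$id)
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- .lnc_truth_row(transcripts$chrom[i], transcripts$start[i],
                         transcripts$end[i], transcripts$strand[i],
                         genes, exons)
    data.frame(id = transcripts$id[i], direction = tr$direction,
               zone = tr$zone, position = tr$position,
               closest_gene = tr$closest, stringsAsFactors = FALSE)
  }))
  list(transcripts = transcripts, seqs = seqs, truth = truth)
}

#' Generate a negative binomial count matrix with planted signal
#'
#' Draws gamma-Poisson (negative binomial) counts for the configured stage
#' design. A fraction `planted_de_fraction` of the non-module features is
#' planted as differentially expressed: their mean is shifted by
#' `planted_fc` (up or down) in one designated stage. Optional co-expression
#' blocks share a latent stage profile, giving correlated features whose
#' eigengene peaks at the block's stage.
#'
#' @param config A [synthetic_config()].
#' @param feature_ids Character vector of feature ids.
#' @param n_modules Number of planted co-expression blocks (0 disables).
#' @param module_size Features per block.
#' @param module_amplitude Log-scale amplitude of the block stage profile.
#' @param base_meanlog,base_sdlog Log-normal parameters for baseline means.
#' @param depth_factors Optional per-sample depth factors (recycled across
#'   samples); default log-normal around 1.
#' @param de_stages Stages eligible as the designated stage of planted
#'   differentially expressed features (default: all stages). Restricting
#'   this to the two stages of a contrast plants the full
#'   `planted_de_fraction` into that contrast.
#' @return List with `counts` (integer matrix features x samples), `design`
#'   (data frame `sample_id`, `stage`, `replicate`), `depth_factors`, and
#'   `truth` (list: `de` data frame with `feature_id`, `stage`, `direction`;
#'   `modules` data frame with `feature_id`, `module`, `peak_stage`).
#' @export
generate_counts <- function(config, feature_ids, n_modules = 2L,
                            module_size = 60L, module_amplitude = log(6),
                            base_meanlog = log(200), base_sdlog = 1,
                            depth_factors = NULL, de_stages = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$nb_dispersion <= 0) stop("generate_counts: nb_dispersion must be > 0")
  set.seed(config$seed + .seed_offset[["counts"]])
  m <- length(feature_ids)
  stages <- config$stage_names
  design <- data.frame(
    sample_id = unlist(lapply(seq_along(stages), function(i) {
      sprintf("%s_R%d", stages[i], seq_len(config$replicates_per_stage[i]))
    })),
    stage = rep(stages, config$replicates_per_stage),
    replicate = unlist(lapply(config$replicates_per_stage, seq_len)),
    stringsAsFactors = FALSE)
  n_samp <- nrow(design)
  if (is.null(depth_factors)) {
    depth_factors <- exp(rnorm(n_samp, 0, 0.15))
  }
  depth_factors <- rep(depth_factors, length.out = n_samp)
  names(depth_factors) <- design$sample_id

  base_mu <- rlnorm(m, base_meanlog, base_sdlog)
  log_mu <- matrix(log(base_mu), m, n_samp)

  module_df <- data.frame(feature_id = character(0), module = integer(0),
                          peak_stage = character(0), stringsAsFactors = FALSE)
  in_module <- rep(FALSE, m)
  if (n_modules > 0) {
    if (n_modules * module_size > m) {
      stop("generate_counts: module blocks exceed the number of features")
    }
    peak <- stages[((seq_len(n_modules) - 1L) %% length(stages)) + 1L]
    idx <- seq_len(n_modules * module_size)
    in_module[idx] <- TRUE
    block <- rep(seq_len(n_modules), each = module_size)
    for (b in seq_len(n_modules)) {
      sel <- idx[block == b]
      log_mu[sel, design$stage == peak[b]] <-
        log_mu[sel, design$stage == peak[b]] + module_amplitude
    }
    module_df <- data.frame(feature_id = feature_ids[idx], module = block,
                            peak_stage = peak[block], stringsAsFactors = FALSE)
  }

  de_df <- data.frame(feature_id = character(0), stage = character(0),
                      direction = integer(0), stringsAsFactors = FALSE)
  pool <- which(!in_module)
  n_de <- round(config$planted_de_fraction * length(pool))
  if (is.null(de_stages)) de_stages <- stages
  stopifnot(all(de_stages %in% stages))
  if (n_de > 0 && config$planted_fc > 1) {
    de_idx <- sample(pool, n_de)
    de_stage <- de_stages[sample.int(length(de_stages), n_de, replace = TRUE)]
    de_dir <- sample(c(1L, -1L), n_de, replace = TRUE)
    for (i in seq_len(n_de)) {
      cols <- design$stage == de_stage[i]
      log_mu[de_idx[i], cols] <- log_mu[de_idx[i], cols] +
        de_dir[i] * log(config$planted_fc)
    }
    de_df <- data.frame(feature_id = feature_ids[de_idx], stage = de_stage,
                        direction = de_dir, stringsAsFactors = FALSE)
  }

  mu <- exp(log_mu) * matrix(depth_factors, m, n_samp, byrow = TRUE)
  counts <- matrix(rnbinom(m * n_samp, mu = mu, size = 1 / config$nb_dispersion),
                   m, n_samp, dimnames = list(feature_ids, design$sample_id))
  list(counts = counts, design = design, depth_factors = depth_factors,
       truth = list(de = de_df, modules = module_df))
}

#' Generate a degradome position profile with planted cleavage peaks
#'
#' Background positions receive sparse low counts; every planted target pair
#' receives a unique maximal peak at its cleavage position (a category-0
#' signature).
#'
#' @param transcript_seqs Named character vector of transcript sequences.
#' @param target_pairs Data frame with `mirna`, `transcript`,
#'   `cleavage_pos` (0-based transcript coordinate).
#' @param seed Integer seed.
#' @param background_rate Fraction of positions carrying background reads.
#' @return Data frame with `transcript`, `position` (0-based), `count`.
#' @export
generate_degradome <- function(transcript_seqs, target_pairs, seed = 1L,
                               background_rate = 0.05) {
  set.seed(as.integer(seed) + .seed_offset[["degradome"]])
  stopifnot(all(target_pairs$transcript %in% names(transcript_seqs)))
  out <- lapply(names(transcript_seqs), function(tx) {
    len <- nchar(transcript_seqs[[tx]])
    n_bg <- max(1L, rbinom(1, len, background_rate))
    pos <- sample.int(len, min(n_bg, len)) - 1L
    cnt <- rpois(length(pos), 1) + 1L
    df <- data.frame(transcript = tx, position = pos, count = cnt,
                     stringsAsFactors = FALSE)
    planted <- target_pairs[target_pairs$transcript == tx, , drop = FALSE]
    if (nrow(planted) > 0) {
      if (any(planted$cleavage_pos < 0 | planted$cleavage_pos >= len)) {
        stop("generate_degradome: cleavage position outside transcript ", tx)
      }
      df <- df[!(df$position %in% planted$cleavage_pos), , drop = FALSE]
      peak <- max(c(df$count, 1L)) + 10L
      df <- rbind(df, data.frame(transcript = tx,
                                 position = planted$cleavage_pos,
                                 count = peak, stringsAsFactors = FALSE))
    }
    df[order(df$position), ]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a complete synthetic dataset to a directory
#'
#' Runs [generate_annotation()], [generate_srna_loci()] and
#' [generate_counts()] and writes every artifact the pipeline consumes:
#' GFF3 gene models, BED repeats and QTL, FASTA reference sets and microRNA
#' sequences, locus and alignment TSVs, count matrix and sample sheet, and a
#' JSON ground-truth sidecar. Byte-identical across runs for a fixed
#' configuration.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
generate_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- generate_annotation(config)
  srna <- generate_srna_loci(config, ann)
  cnt <- generate_counts(config, srna$loci$id)

  paths <- list(
    genes = file.path(dir, "genes.gff3"),
    repeats = file.path(dir, "repeats.bed"),
    qtl = file.path(dir, "qtl.bed"),
    mirnas = file.path(dir, "mirnas.fa"),
    loci = file.path(dir, "srna_loci.tsv"),
    alignments = file.path(dir, "srna_alignments.tsv"),
    locus_seqs = file.path(dir, "locus_seqs.fa"),
    counts = file.path(dir, "srna_counts.tsv"),
    samples = file.path(dir, "sample_sheet.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  write_genes_gff3(ann$genes, ann$exons, paths$genes)
  write_bed(ann$repeats, paths$repeats)
  write_bed(ann$qtl, paths$qtl)
  write_fasta(ann$mirnas, paths$mirnas)
  ref_dir <- file.path(dir, "class_refs")
  dir.create(ref_dir, showWarnings = FALSE)
  for (cl in names(ann$class_refs)) {
    write_fasta(ann$class_refs[[cl]],
                file.path(ref_dir, paste0(sub("-", "_", cl), ".fa")))
  }
  write_tsv(srna$loci, paths$loci)
  write_tsv(srna$alignments, paths$alignments)
  write_fasta(srna$locus_seqs, paths$locus_seqs)
  write_counts(cnt$counts, paths$counts)
  write_tsv(cnt$design, paths$samples)
  truth <- c(srna$truth, list(de = cnt$truth$de, modules = cnt$truth$modules))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(annotation = ann, srna = srna, counts = cnt, paths = paths))
}
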