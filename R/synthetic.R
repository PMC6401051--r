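#' Configuration for the synthetic study generator
#'
#' The defaults state the world the generator emulates: a 3-tissue,
#' 10-condition (4 leaf + 3 inflorescence + 3 berry stages), 3-replicate
#' expression study over a pool of 100 coding and 100 non-coding
#' transcripts laid out on a small multi-chromosome genome, with planted
#' condition-specific, differentially expressed and co-expressed
#' transcripts and planted miRNA target sites, embedded hairpins and eTM
#' sites. The seed fixes every byte of the emitted bundle.
#'
#' @param seed Integer RNG seed.
#' @param n_chromosomes,chrom_length Genome layout.
#' @param n_coding,n_noncoding Transcript pool composition.
#' @param n_conditions,n_replicates Study design (10 conditions reproduce
#'   the leaf/inflorescence/berry staging; other values get generic
#'   labels).
#' @param n_specific Planted condition-specific transcripts.
#' @param specificity_target Planted specificity index (in
#'   `(1/n_conditions, 1]`).
#' @param n_de_pairs Planted `de_fold`-fold differentially expressed
#'   transcripts.
#' @param de_fold Planted fold change (default 8, twice the 4-fold
#'   detection threshold).
#' @param n_coexpr_pairs Planted lncRNA-mRNA pairs with noiseless shared
#'   condition profiles.
#' @param n_cp_coexpr,n_mt_coexpr Planted lncRNA-organelle-CDS pairs.
#' @param n_mirnas,n_target_sites,n_precursor_embeddings,n_etm_sites
#'   Planted miRNA interactions.
#' @param n_organelle_homology Planted lncRNA/organelle shared segments
#'   (> 200 nt).
#' @param n_chloroplast_cds,n_mitochondrial_cds Organelle CDS pool sizes.
#' @param fpkm_noise_cv Coefficient of variation of the multiplicative
#'   log-normal replicate noise (0 = noiseless).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 10L,
                       chrom_length = 150000L, n_coding = 100L,
                       n_noncoding = 100L, n_conditions = 10L,
                       n_replicates = 3L, n_specific = 10L,
                       specificity_target = 0.8, n_de_pairs = 10L,
                       de_fold = 8, n_coexpr_pairs = 10L,
                       n_cp_coexpr = 2L, n_mt_coexpr = 2L,
                       n_mirnas = 10L, n_target_sites = 8L,
                       n_precursor_embeddings = 5L, n_etm_sites = 5L,
                       n_organelle_homology = 2L,
                       n_chloroplast_cds = 8L, n_mitochondrial_cds = 6L,
                       fpkm_noise_cv = 0.1) {
  cfg <- as.list(environment())
  counts <- cfg[grepl("^n_", names(cfg))]
  if (any(unlist(counts) < 0)) stop("all counts must be >= 0")
  if (n_conditions < 2L) stop("need at least 2 conditions")
  if (specificity_target <= 1 / n_conditions || specificity_target > 1) {
    stop("specificity_target must be in (1/n_conditions, 1]")
  }
  n_seq_hosts <- n_target_sites + n_precursor_embeddings + n_etm_sites +
    n_organelle_homology
  n_expr_hosts <- n_specific + n_de_pairs + n_coexpr_pairs +
    n_cp_coexpr + n_mt_coexpr
  if (n_seq_hosts + n_expr_hosts > n_noncoding) {
    stop("planted features exceed available non-coding transcripts")
  }
  if (n_coexpr_pairs > n_coding) {
    stop("more co-expression pairs than coding partners")
  }
  if (n_cp_coexpr > n_chloroplast_cds || n_mt_coexpr > n_mitochondrial_cds) {
    stop("more organelle pairs than organelle CDS")
  }
  if (fpkm_noise_cv < 0) stop("fpkm_noise_cv must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Plant an exact specificity index into a consensus row
#'
#' Rescales a row so that, keeping the row total, the focal condition
#' holds `index_target` of the total and the remainder is split evenly —
#' the quotient definition then returns exactly `index_target`.
#'
#' @param base_row Named numeric consensus row.
#' @param condition Focal condition (name or index).
#' @param index_target Target specificity index, in
#'   `(1/length(base_row), 1]`.
#' @return Modified row with the same total.
#' @export
plant_specific_profile <- function(base_row, condition,
                                   index_target = 0.8) {
  n <- length(base_row)
  if (index_target <= 1 / n) {
    stop("index_target must exceed 1/n_conditions (not specific)")
  }
  if (index_target > 1) stop("index_target must be <= 1")
  k <- if (is.character(condition)) match(condition, names(base_row))
       else as.integer(condition)
  if (is.na(k) || k < 1L || k > n) stop("unknown focal condition")
  total <- sum(base_row)
  out <- rep(total * (1 - index_target) / (n - 1L), n)
  out[k] <- total * index_target
  names(out) <- names(base_row)
  out
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

# Coding transcript: 5' UTR + ATG + (codons-1) non-stop codons + stop +
# 3' UTR; its longest ORF is >= `codons` aa by construction.
make_coding_seq <- function(codons) {
  orf <- paste0("ATG",
                paste(sample(NON_STOP_CODONS, codons - 1L, replace = TRUE),
                      collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  paste0(rand_seq(sample(20:80, 1L)), orf, rand_seq(sample(20:120, 1L)))
}

condition_design <- function(n_conditions) {
  if (n_conditions == 10L) {
    data.frame(
      tissue = c(rep("leaf", 4L), rep("inflorescence", 3L),
                 rep("berry", 3L)),
      stage = c("young", "expanding", "mature", "senescent",
                "well_developed", "cap_fall_100pct", "post_cap_fall_7d",
                "fruit_set", "veraison", "ripe"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      tissue = rep(c("leaf", "inflorescence", "berry"),
                   length.out = n_conditions),
      stage = paste0("stage", seq_len(n_conditions)),
      stringsAsFactors = FALSE)
  }
}

# --- genome scratch pad -----------------------------------------------------

new_genome <- function(n_chrom, chrom_length) {
  g <- lapply(seq_len(n_chrom), function(i)
    sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE))
  names(g) <- paste0("chr", seq_len(n_chrom))
  g
}

seg_write <- function(genome, chrom, start0, seq) {
  genome[[chrom]][(start0 + 1L):(start0 + nchar(seq))] <-
    chars(toupper(seq))
  genome
}

seg_read <- function(genome, chrom, start0, end0) {
  paste(genome[[chrom]][(start0 + 1L):end0], collapse = "")
}

# transcript sequence at a single-exon locus, strand-aware
locus_seq <- function(genome, locus) {
  s <- seg_read(genome, locus$chrom, locus$start, locus$end)
  if (locus$strand == "+") s else revcomp(s)
}

# write a transcript sequence back into the genome through its locus
locus_write <- function(genome, locus, seq) {
  seg_write(genome, locus$chrom, locus$start,
            if (locus$strand == "+") seq else revcomp(seq))
}

overlaps_any <- function(occ, start, end, margin = 0) {
  if (nrow(occ) == 0L) return(FALSE)
  any(start - margin < occ[, 2L] & occ[, 1L] < end + margin)
}

# --- the generator ----------------------------------------------------------

#' Generate a synthetic lncRNA study bundle with a ground-truth manifest
#'
#' Emits a fully self-consistent bundle: genome FASTA, reference gene
#' annotation (GTF), transcript FASTA (coding + non-coding), replicate
#' FPKM expression matrix with sample metadata, mature miRNA and hairpin
#' FASTA, organelle CDS FASTA, a transcription-factor id list, and stub
#' external-tool tables (coding-potential scores, protein-homology hits,
#' genome alignments) consistent with the planted loci. Every claim in
#' the returned manifest is re-derivable from the emitted files by the
#' downstream modules. Identical configurations produce byte-identical
#' bundles.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory; when given, all bundle files
#'   and the manifest (TSV + JSON) are written there.
#' @return A list (invisible when writing) with the in-memory bundle:
#'   `transcripts`, `genome_records`, `reference_models`, `fpkm`,
#'   `samples`, `consensus_true`, `mirnas`, `hairpins`, `cp_cds`,
#'   `mt_cds`, `tf_ids`, `score_table`, `protein_hits`, `genome_hits`,
#'   `manifest`, and `paths` (when written).
#' @export
simulate_study <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  nC <- cfg$n_conditions

  # ---- study design
  cond <- condition_design(nC)
  cond$condition <- paste(cond$tissue, cond$stage, sep = ".")
  samples <- do.call(rbind, lapply(seq_len(nC), function(i) {
    data.frame(sample = paste0(cond$condition[[i]], "_R",
                               seq_len(cfg$n_replicates)),
               tissue = cond$tissue[[i]], stage = cond$stage[[i]],
               replicate = seq_len(cfg$n_replicates),
               stringsAsFactors = FALSE)
  }))
  samples$condition <- paste(samples$tissue, samples$stage, sep = ".")

  # ---- miRNAs and hairpins
  mirna_ids <- sprintf("sim-miR%03d", seq_len(cfg$n_mirnas))
  mirna_seqs <- vapply(seq_len(cfg$n_mirnas), function(i) rand_seq(21L),
                       character(1))
  hairpin_ids <- paste0(mirna_ids, "-hp")
  hairpin_seqs <- vapply(seq_len(cfg$n_mirnas), function(i) {
    paste0(mirna_seqs[[i]], rand_seq(8L), revcomp(mirna_seqs[[i]]))
  }, character(1))

  # ---- organelle CDS (synthetic stand-ins: random sequences, no real
  # ORF structure; only their ids, lengths and expression matter)
  cp_ids <- sprintf("cpCDS_%03d", seq_len(cfg$n_chloroplast_cds))
  mt_ids <- sprintf("mtCDS_%03d", seq_len(cfg$n_mitochondrial_cds))
  cp_seqs <- vapply(cp_ids, function(i) rand_seq(sample(300:900, 1L)),
                    character(1))
  mt_seqs <- vapply(mt_ids, function(i) rand_seq(sample(300:900, 1L)),
                    character(1))

  # ---- genome and coding gene models (2 exons, intron 2000-4000 nt)
  genome <- new_genome(cfg$n_chromosomes, cfg$chrom_length)
  chroms <- names(genome)
  occupied <- setNames(lapply(chroms, function(x)
    matrix(numeric(0), ncol = 2)), chroms)
  gene_spans <- occupied

  # `occupied` tracks lncRNA loci only; `gene_spans` tracks gene bodies
  place_interval <- function(len, margin = 10, clear_of_genes = 0,
                             max_try = 500L) {
    for (i in seq_len(max_try)) {
      ch <- sample(chroms, 1L)
      if (cfg$chrom_length - len - 2L < 1L) next
      s <- sample.int(cfg$chrom_length - len - 1L, 1L)
      if (overlaps_any(occupied[[ch]], s, s + len, margin)) next
      if (overlaps_any(gene_spans[[ch]], s, s + len,
                       max(clear_of_genes, margin))) next
      return(list(chrom = ch, start = s, end = s + len))
    }
    stop("could not place an interval of length ", len,
         "; increase chrom_length or n_chromosomes")
  }

  coding_ids <- sprintf("mRNA_%03d", seq_len(cfg$n_coding))
  coding_seqs <- character(cfg$n_coding)
  coding_orf_aa <- integer(cfg$n_coding)
  ref_models <- list()
  coding_hits <- list()
  for (i in seq_len(cfg$n_coding)) {
    codons <- sample(150:400, 1L)
    s <- make_coding_seq(codons)
    coding_seqs[[i]] <- s
    coding_orf_aa[[i]] <- codons
    len <- nchar(s)
    e1 <- floor(len * runif(1, 0.4, 0.6))
    intron <- sample(2000:4000, 1L)
    strand <- sample(c("+", "-"), 1L)
    span <- place_interval(e1 + intron + (len - e1), margin = 50)
    ch <- span$chrom
    ex <- rbind(c(span$start, span$start + e1),
                c(span$start + e1 + intron, span$end))
    # genomic sequence: spliced '+' reads the transcript, '-' reads its
    # reverse complement
    gseq <- if (strand == "+") s else revcomp(s)
    genome <- seg_write(genome, ch, ex[1L, 1L], substr(gseq, 1L, e1))
    genome <- seg_write(genome, ch, ex[2L, 1L],
                        substr(gseq, e1 + 1L, len))
    gene_spans[[ch]] <- rbind(gene_spans[[ch]], c(span$start, span$end))
    ref_models[[coding_ids[[i]]]] <-
      transcript_model(coding_ids[[i]], ch, strand, ex,
                       gene_id = sub("mRNA", "gene", coding_ids[[i]]))
    # per-exon genome hits (query coordinates on the transcript)
    qr <- if (strand == "+") list(c(1L, e1), c(e1 + 1L, len))
          else list(c(len - e1 + 1L, len), c(1L, len - e1))
    for (k in 1:2) {
      elen <- ex[k, 2L] - ex[k, 1L]
      sstt <- if (strand == "+") c(ex[k, 1L] + 1L, ex[k, 2L])
              else c(ex[k, 2L], ex[k, 1L] + 1L)
      coding_hits[[length(coding_hits) + 1L]] <- data.frame(
        query_id = coding_ids[[i]], subject_id = ch,
        percent_identity = 100, align_length = elen, mismatches = 0L,
        gap_opens = 0L, q_start = qr[[k]][1L], q_end = qr[[k]][2L],
        s_start = sstt[[1L]], s_end = sstt[[2L]], evalue = 0,
        bit_score = 2 * elen, stringsAsFactors = FALSE)
    }
  }

  # ---- non-coding transcripts: class-code layout
  N <- cfg$n_noncoding
  nc_ids <- sprintf("lnc_%03d", seq_len(N))
  n_i <- round(0.29 * N); n_x <- round(0.14 * N)
  codes <- sample(c(rep("i", n_i), rep("x", n_x),
                    rep("u", N - n_i - n_x)))
  nc_len <- sample(250:1500, N, replace = TRUE)

  # host assignment for sequence-level plants happens before locus
  # placement so host lengths can be guaranteed. Never on 'x' hosts:
  # their overlapped exon bases are fixed by the host gene.
  free <- which(codes != "x")
  need <- cfg$n_target_sites + cfg$n_precursor_embeddings +
    cfg$n_etm_sites + cfg$n_organelle_homology
  if (length(free) < need) stop("not enough non-antisense hosts")
  tgt_host <- free[seq_len(cfg$n_target_sites)]
  free <- setdiff(free, tgt_host)
  pre_host <- free[seq_len(cfg$n_precursor_embeddings)]
  free <- setdiff(free, pre_host)
  etm_host <- free[seq_len(cfg$n_etm_sites)]
  free <- setdiff(free, etm_host)
  org_host <- free[seq_len(cfg$n_organelle_homology)]
  # organelle-homology hosts carry a 300-nt shared segment
  nc_len[org_host] <- pmax(nc_len[org_host], 400L)

  nc_locus <- vector("list", N)
  for (i in seq_len(N)) {
    len <- nc_len[[i]]
    if (codes[[i]] == "u") {
      sp <- place_interval(len, margin = 10, clear_of_genes = 2100)
      nc_locus[[i]] <- list(chrom = sp$chrom, start = sp$start,
                            end = sp$end, strand = sample(c("+", "-"), 1L))
      occupied[[sp$chrom]] <- rbind(occupied[[sp$chrom]],
                                    c(sp$start, sp$end))
    } else if (codes[[i]] == "i") {
      placed <- FALSE
      for (try in seq_len(500L)) {
        g <- ref_models[[sample(coding_ids, 1L)]]
        intr <- model_introns(g)[1L, ]
        if (intr[[2L]] - intr[[1L]] < len + 4L) next
        s <- intr[[1L]] + 1L +
          sample.int(intr[[2L]] - intr[[1L]] - len - 2L, 1L)
        if (overlaps_any(occupied[[g$chrom]], s, s + len, 5)) next
        nc_locus[[i]] <- list(chrom = g$chrom, start = s, end = s + len,
                              strand = g$strand)
        occupied[[g$chrom]] <- rbind(occupied[[g$chrom]], c(s, s + len))
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place intronic lncRNA ", nc_ids[[i]])
    } else { # 'x': antisense exon overlap, capped at 300 shared nt
      placed <- FALSE
      for (try in seq_len(500L)) {
        g <- ref_models[[sample(coding_ids, 1L)]]
        ex <- g$exons[sample(1:2, 1L), ]
        ov <- sample(60:min(300L, ex[[2L]] - ex[[1L]], len - 10L), 1L)
        s <- ex[[2L]] - ov  # overlap the exon tail, extend rightward
        e <- s + len
        if (e > cfg$chrom_length - 1L) next
        # allowed to overlap the host gene only
        span <- gene_spans[[g$chrom]]
        host <- which(span[, 1L] == g$exons[1L, 1L] &
                      span[, 2L] == g$exons[nrow(g$exons), 2L])[1]
        if (overlaps_any(span[-host, , drop = FALSE], s, e, 2100)) next
        if (overlaps_any(occupied[[g$chrom]], s, e, 5)) next
        nc_locus[[i]] <- list(chrom = g$chrom, start = s, end = e,
                              strand = if (g$strand == "+") "-" else "+",
                              host_exon = ex, host = g$id)
        occupied[[g$chrom]] <- rbind(occupied[[g$chrom]], c(s, e))
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place antisense lncRNA ", nc_ids[[i]])
    }
  }

  mirna_of <- function(k) ((k - 1L) %% cfg$n_mirnas) + 1L

  # ---- generate non-coding sequences (ORF-bounded, with plants)
  nc_seq <- character(N)
  interactions <- list()
  org_homology <- list()
  for (i in seq_len(N)) {
    loc <- nc_locus[[i]]
    len <- nc_len[[i]]
    insert <- NULL
    if (i %in% tgt_host) {
      k <- mirna_of(match(i, tgt_host))
      insert <- list(kind = "target", mirna = k,
                     seq = revcomp(mirna_seqs[[k]]))
    } else if (i %in% pre_host) {
      k <- mirna_of(match(i, pre_host))
      insert <- list(kind = "precursor", mirna = k,
                     seq = hairpin_seqs[[k]])
    } else if (i %in% etm_host) {
      k <- mirna_of(match(i, etm_host))
      m <- mirna_seqs[[k]]
      insert <- list(kind = "eTM", mirna = k,
                     seq = paste0(revcomp(substr(m, 11L, 21L)),
                                  rand_seq(3L),
                                  revcomp(substr(m, 1L, 10L))))
    } else if (i %in% org_host) {
      k <- match(i, org_host)
      src_id <- if (k %% 2L == 1L) cp_ids[[1L + (k - 1L) %/% 2L]]
                else mt_ids[[1L + (k - 1L) %/% 2L]]
      src <- if (k %% 2L == 1L) cp_seqs[[1L + (k - 1L) %/% 2L]]
             else mt_seqs[[1L + (k - 1L) %/% 2L]]
      seg_len <- min(300L, nchar(src))
      seg_at <- sample.int(nchar(src) - seg_len + 1L, 1L)
      insert <- list(kind = "organelle", source = src_id,
                     seq = substr(src, seg_at, seg_at + seg_len - 1L))
    }
    ins_len <- if (is.null(insert)) 0L else nchar(insert$seq)
    if (ins_len + 40L > len) {
      # grow the transcript so the plant fits (keeps the locus honest)
      stop("planted feature longer than host transcript ", nc_ids[[i]])
    }
    fixed_tail <- NULL
    if (codes[[i]] == "x") {
      # keep the exon-overlapping bases as already written to the genome
      ov_len <- loc$host_exon[[2L]] - loc$start
      gfix <- seg_read(genome, loc$chrom, loc$start, loc$host_exon[[2L]])
      fixed_head <- if (loc$strand == "+") gfix else NULL
      fixed_tail <- if (loc$strand == "-") revcomp(gfix) else NULL
    }
    for (try in seq_len(200L)) {
      s <- rand_seq(len)
      if (codes[[i]] == "x") {
        ov_len <- loc$host_exon[[2L]] - loc$start
        if (loc$strand == "+") {
          s <- paste0(seg_read(genome, loc$chrom, loc$start,
                               loc$host_exon[[2L]]),
                      substr(s, ov_len + 1L, len))
        } else {
          s <- paste0(substr(s, 1L, len - ov_len),
                      revcomp(seg_read(genome, loc$chrom, loc$start,
                                       loc$host_exon[[2L]])))
        }
      }
      pos <- NA_integer_
      if (!is.null(insert)) {
        lo <- if (codes[[i]] == "x" && loc$strand == "+")
          300L + 20L else 20L  # keep plants clear of fixed 'x' bases
        hi <- len - ins_len - 20L
        if (codes[[i]] == "x" && loc$strand == "-") hi <- hi - 300L
        pos <- sample(lo:hi, 1L)
        s <- paste0(substr(s, 1L, pos - 1L), insert$seq,
                    substr(s, pos + ins_len, len))
      }
      if (max_orf_aa(s) <= 100L) break
      if (try == 200L) stop("could not bound ORFs in ", nc_ids[[i]])
    }
    nc_seq[[i]] <- s
    genome <- locus_write(genome, loc, s)
    if (!is.null(insert)) {
      if (insert$kind == "organelle") {
        org_homology[[length(org_homology) + 1L]] <- data.frame(
          lncRNA_id = nc_ids[[i]], organelle_id = insert$source,
          start = pos - 1L, end = pos - 1L + ins_len,
          stringsAsFactors = FALSE)
      } else {
        interactions[[length(interactions) + 1L]] <- data.frame(
          kind = insert$kind, mirna_id = mirna_ids[[insert$mirna]],
          lncRNA_id = nc_ids[[i]], start = pos - 1L,
          end = pos - 1L + ins_len, stringsAsFactors = FALSE)
        if (insert$kind == "precursor") {
          # the 3' hairpin arm is a perfect target site for the mature
          # miRNA: record it so recovery accounting is exact
          interactions[[length(interactions) + 1L]] <- data.frame(
            kind = "target", mirna_id = mirna_ids[[insert$mirna]],
            lncRNA_id = nc_ids[[i]], start = pos - 1L + 29L,
            end = pos - 1L + 50L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  interactions <- if (length(interactions) > 0L)
    do.call(rbind, interactions) else
    data.frame(kind = character(0), mirna_id = character(0),
               lncRNA_id = character(0), start = integer(0),
               end = integer(0))
  org_homology <- if (length(org_homology) > 0L)
    do.call(rbind, org_homology) else
    data.frame(lncRNA_id = character(0), organelle_id = character(0),
               start = integer(0), end = integer(0))

  # ---- expression: noiseless consensus with enforced separation margins
  all_ids <- c(coding_ids, nc_ids, cp_ids, mt_ids)
  conds <- cond$condition
  consensus <- matrix(0, nrow = length(all_ids), ncol = nC,
                      dimnames = list(all_ids, conds))
  flat_profile <- function() {
    for (try in seq_len(100L)) {
      base <- rlnorm(1L, meanlog = log(8), sdlog = 1.2)
      row <- base * exp(rnorm(nC, 0, 0.05))
      if (max(row) / min(row) < 2) return(row)
    }
    stop("could not draw a flat profile")
  }
  shared_profile <- function() {
    # strongly varying (drives the correlation), mean >= 40, and
    # unambiguously DE (>= 16-fold dynamic range above a 2-FPKM floor,
    # so several pairwise comparisons clear the 4-fold threshold under
    # replicate noise) but never condition-specific (max index <= 0.6)
    for (try in seq_len(5000L)) {
      row <- rlnorm(nC, meanlog = log(60), sdlog = 0.9)
      if (mean(row) >= 40 && min(row) >= 2 &&
          max(row) / min(row) >= 16 && max(row) / sum(row) <= 0.6) {
        return(row)
      }
    }
    stop("could not draw a shared profile")
  }
  for (id in all_ids) consensus[id, ] <- flat_profile()

  nc_specific <- rep(NA_character_, N)
  nc_de <- rep(FALSE, N)
  expr_free <- setdiff(seq_len(N),
                       c(tgt_host, pre_host, etm_host, org_host))
  take <- function(n) {
    out <- expr_free[seq_len(n)]
    expr_free <<- setdiff(expr_free, out)
    out
  }
  spec_host <- take(cfg$n_specific)
  de_host <- take(cfg$n_de_pairs)
  coex_host <- take(cfg$n_coexpr_pairs)
  cp_host <- take(cfg$n_cp_coexpr)
  mt_host <- take(cfg$n_mt_coexpr)

  for (i in spec_host) {
    total <- runif(1, 80, 250)  # below the mean-30 co-expression filter
    focal <- sample(conds, 1L)
    consensus[nc_ids[[i]], ] <- plant_specific_profile(
      setNames(rep(total / nC, nC), conds), focal,
      cfg$specificity_target)
    nc_specific[[i]] <- focal
    nc_de[[i]] <- TRUE  # a 0.8-index profile is trivially >= 4-fold DE
  }
  for (i in de_host) {
    # baseline kept below the mean-30 co-expression filter: the spiky
    # DE profile would otherwise correlate with any partner profile
    # peaking in the same condition
    row <- runif(1, 5, 15) * exp(rnorm(nC, 0, 0.05))
    focal <- sample.int(nC, 1L)
    row[[focal]] <- row[[focal]] * cfg$de_fold
    consensus[nc_ids[[i]], ] <- row
    nc_de[[i]] <- TRUE
  }
  coex_partner <- rep(NA_character_, N)
  partner_pool <- sample(coding_ids, cfg$n_coexpr_pairs)
  for (k in seq_along(coex_host)) {
    i <- coex_host[[k]]
    prof <- shared_profile()
    consensus[nc_ids[[i]], ] <- prof
    consensus[partner_pool[[k]], ] <- prof
    coex_partner[[i]] <- partner_pool[[k]]
    nc_de[[i]] <- TRUE
  }
  org_partner <- rep(NA_character_, N)
  for (k in seq_along(cp_host)) {
    i <- cp_host[[k]]
    prof <- shared_profile()
    consensus[nc_ids[[i]], ] <- prof
    consensus[cp_ids[[k]], ] <- prof
    org_partner[[i]] <- cp_ids[[k]]
    nc_de[[i]] <- TRUE
  }
  for (k in seq_along(mt_host)) {
    i <- mt_host[[k]]
    prof <- shared_profile()
    consensus[nc_ids[[i]], ] <- prof
    consensus[mt_ids[[k]], ] <- prof
    org_partner[[i]] <- mt_ids[[k]]
    nc_de[[i]] <- TRUE
  }

  # TFs: every second co-expression partner, plus unpartnered extras
  tf_planted <- partner_pool[seq_along(partner_pool) %% 2L == 1L]
  tf_extra <- head(setdiff(coding_ids, partner_pool), 5L)
  tf_ids <- sort(unique(c(tf_planted, tf_extra)))

  # replicate matrix with multiplicative log-normal noise of the stated CV
  n_samp <- nrow(samples)
  fpkm <- matrix(0, nrow = length(all_ids), ncol = n_samp,
                 dimnames = list(all_ids, samples$sample))
  if (cfg$fpkm_noise_cv > 0) {
    sdl <- sqrt(log(1 + cfg$fpkm_noise_cv^2))
    noise <- matrix(rlnorm(length(all_ids) * n_samp,
                           meanlog = -sdl^2 / 2, sdlog = sdl),
                    nrow = length(all_ids))
  } else {
    noise <- matrix(1, nrow = length(all_ids), ncol = n_samp)
  }
  for (j in seq_len(n_samp)) {
    fpkm[, j] <- consensus[, samples$condition[[j]]] * noise[, j]
  }

  # ---- stub external tables
  score_table <- setNames(
    c(runif(cfg$n_coding, 1, 3), -runif(N, 0.5, 3),
      runif(length(cp_ids) + length(mt_ids), 1, 3)),
    c(coding_ids, nc_ids, cp_ids, mt_ids))
  protein_hits <- data.frame(
    query_id = coding_ids,
    subject_id = sprintf("PROT_%03d", seq_len(cfg$n_coding)),
    percent_identity = round(runif(cfg$n_coding, 85, 99), 1),
    align_length = coding_orf_aa, mismatches = 0L, gap_opens = 0L,
    q_start = 1L, q_end = coding_orf_aa * 3L, s_start = 1L,
    s_end = coding_orf_aa, evalue = 1e-50,
    bit_score = round(coding_orf_aa * 1.9, 1), stringsAsFactors = FALSE)
  nc_hits <- do.call(rbind, lapply(seq_len(N), function(i) {
    loc <- nc_locus[[i]]
    len <- nc_len[[i]]
    sstt <- if (loc$strand == "+") c(loc$start + 1L, loc$end)
            else c(loc$end, loc$start + 1L)
    data.frame(query_id = nc_ids[[i]], subject_id = loc$chrom,
               percent_identity = 100, align_length = len,
               mismatches = 0L, gap_opens = 0L, q_start = 1L,
               q_end = len, s_start = sstt[[1L]], s_end = sstt[[2L]],
               evalue = 0, bit_score = 2 * len, stringsAsFactors = FALSE)
  }))
  genome_hits <- rbind(do.call(rbind, coding_hits), nc_hits)

  # ---- assemble
  transcripts <- seq_set(c(coding_ids, nc_ids),
                         c(coding_ids, nc_ids),
                         c(coding_seqs, nc_seq))
  genome_records <- seq_set(chroms, chroms,
                            vapply(genome, paste, character(1),
                                   collapse = ""))
  manifest_tx <- data.frame(
    id = c(coding_ids, nc_ids),
    type = c(rep("coding", cfg$n_coding), rep("noncoding", N)),
    length = c(nchar(coding_seqs), nc_len),
    max_orf_aa = c(coding_orf_aa,
                   vapply(nc_seq, max_orf_aa, integer(1),
                          USE.NAMES = FALSE)),
    chrom = c(vapply(ref_models, `[[`, character(1), "chrom"),
              vapply(nc_locus, `[[`, character(1), "chrom")),
    strand = c(vapply(ref_models, `[[`, character(1), "strand"),
               vapply(nc_locus, `[[`, character(1), "strand")),
    start = c(vapply(ref_models, function(m) m$exons[1L, 1L], numeric(1)),
              vapply(nc_locus, `[[`, numeric(1), "start")),
    end = c(vapply(ref_models, function(m) m$exons[nrow(m$exons), 2L],
                   numeric(1)),
            vapply(nc_locus, `[[`, numeric(1), "end")),
    class_code = c(rep(NA_character_, cfg$n_coding), codes),
    specific_condition = c(rep(NA_character_, cfg$n_coding), nc_specific),
    de_expected = c(rep(NA, cfg$n_coding), nc_de),
    coexpr_partner = c(rep(NA_character_, cfg$n_coding), coex_partner),
    organelle_partner = c(rep(NA_character_, cfg$n_coding), org_partner),
    stringsAsFactors = FALSE)

  manifest <- list(
    config = unclass(cfg),
    transcripts = manifest_tx,
    interactions = interactions,
    organelle_homology = org_homology,
    coexpr_pairs = data.frame(
      lncRNA_id = nc_ids[coex_host],
      partner_id = partner_pool,
      partner_is_tf = partner_pool %in% tf_ids,
      stringsAsFactors = FALSE),
    organelle_pairs = data.frame(
      lncRNA_id = nc_ids[c(cp_host, mt_host)],
      partner_id = c(cp_ids[seq_along(cp_host)],
                     mt_ids[seq_along(mt_host)]),
      organelle = c(rep("chloroplast", length(cp_host)),
                    rep("mitochondrion", length(mt_host))),
      stringsAsFactors = FALSE),
    counts = list(
      coding = cfg$n_coding, noncoding = N,
      specific = cfg$n_specific,
      de = sum(nc_de),
      coexpr_edges = cfg$n_coexpr_pairs,
      tf_edges = sum(partner_pool %in% tf_ids),
      cp_edges = cfg$n_cp_coexpr, mt_edges = cfg$n_mt_coexpr,
      target_lnc = length(unique(
        interactions$lncRNA_id[interactions$kind == "target"])),
      precursor_lnc = length(unique(
        interactions$lncRNA_id[interactions$kind == "precursor"])),
      etm_lnc = length(unique(
        interactions$lncRNA_id[interactions$kind == "eTM"])),
      organelle_homology = nrow(org_homology)))

  bundle <- list(
    config = cfg, transcripts = transcripts,
    genome_records = genome_records, reference_models = ref_models,
    fpkm = fpkm, samples = samples, consensus_true = consensus,
    mirnas = seq_set(mirna_ids, mirna_ids, mirna_seqs),
    hairpins = seq_set(hairpin_ids, hairpin_ids, hairpin_seqs),
    cp_cds = seq_set(cp_ids, cp_ids, unname(cp_seqs)),
    mt_cds = seq_set(mt_ids, mt_ids, unname(mt_seqs)),
    tf_ids = tf_ids, score_table = score_table,
    protein_hits = protein_hits, genome_hits = genome_hits,
    manifest = manifest)

  if (!is.null(outdir)) {
    bundle$paths <- write_bundle(bundle, outdir)
    return(invisible(bundle))
  }
  bundle
}

#' Write a simulated bundle to disk
#'
#' @param bundle Output of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(x) file.path(outdir, x)
  write_fasta(bundle$genome_records, p("genome.fa"))
  write_fasta(bundle$transcripts, p("transcripts.fa"))
  write_gtf(bundle$reference_models, p("reference.gtf"))
  write_fasta(bundle$mirnas, p("mirna_mature.fa"))
  write_fasta(bundle$hairpins, p("mirna_hairpin.fa"))
  write_fasta(bundle$cp_cds, p("chloroplast_cds.fa"))
  write_fasta(bundle$mt_cds, p("mitochondrial_cds.fa"))
  writeLines(bundle$tf_ids, p("tf_ids.txt"))
  expr <- data.frame(transcript_id = rownames(bundle$fpkm),
                     bundle$fpkm, check.names = FALSE)
  write_tsv(expr, p("expression.tsv"))
  write_tsv(bundle$samples[c("sample", "tissue", "stage", "replicate")],
            p("samples.tsv"))
  write_tsv(data.frame(transcript_id = names(bundle$score_table),
                       score = unname(bundle$score_table)),
            p("coding_scores.tsv"))
  write.table(bundle$protein_hits, p("protein_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(bundle$genome_hits, p("genome_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(bundle$manifest$transcripts, p("manifest_transcripts.tsv"))
  write_tsv(bundle$manifest$interactions, p("manifest_interactions.tsv"))
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(setNames(
    p(c("genome.fa", "transcripts.fa", "reference.gtf",
        "mirna_mature.fa", "mirna_hairpin.fa", "chloroplast_cds.fa",
        "mitochondrial_cds.fa", "tf_ids.txt", "expression.tsv",
        "samples.tsv", "coding_scores.tsv", "protein_hits.tsv",
        "genome_hits.tsv", "manifest_transcripts.tsv",
        "manifest_interactions.tsv", "manifest.json")),
    c("genome", "transcripts", "reference_gtf", "mirna_mature",
      "mirna_hairpin", "cp_cds", "mt_cds", "tf_ids", "expression",
      "samples", "coding_scores", "protein_hits", "genome_hits",
      "manifest_transcripts", "manifest_interactions", "manifest")))
}
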