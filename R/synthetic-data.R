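#' Default TE plan for the toy genome
#'
#' Per-subfamily locus counts, taxonomy and length ranges used by
#' [simulate_annotation()]. LTR subfamilies dominate (the LTR12C-like
#' subfamily carries the planted chimeric-transcript and peak signal, plus
#' full-length ERV9-like elements), with SINE/LINE subfamilies added for
#' catalog realism.
#'
#' @return A data.frame with one row per subfamily.
#' @export
default_te_plan <- function() {
  data.frame(
    subfamily = c("LTR12C", "THE1B", "MLT1D", "THE1C", "LTR7",
                  "AluY", "L1HS"),
    family = c("ERV9", "MaLR", "MaLR", "MaLR", "HERVH", "Alu", "L1"),
    class = c("LTR", "LTR", "LTR", "LTR", "LTR", "SINE", "LINE"),
    n_solo = c(40L, 40L, 40L, 30L, 30L, 60L, 20L),
    n_full = c(6L, 0L, 0L, 0L, 4L, 0L, 0L),
    min_len = c(1000L, 350L, 400L, 350L, 400L, 280L, 900L),
    max_len = c(1600L, 420L, 500L, 420L, 480L, 320L, 2000L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic dataset: a toy genome, gene
#' models, the TE plan with fragmentation and full-length ERV structure,
#' planted transpochimeric transcripts and decoys, peak sets with a planted
#' subfamily enrichment, temporal expression patterns (maternal vs ZGA) and
#' CpG methylation with a planted between-set difference. One integer seed
#' drives everything; each generator stage derives its own deterministic
#' substream so that regenerating one stage does not perturb the others.
#'
#' @param seed Integer seed for all randomness.
#' @param genome Named vector of chromosome lengths (bp).
#' @param n_genes Number of 3-exon gene models.
#' @param te_plan Data.frame as returned by [default_te_plan()].
#' @param ltr_int_pairs Named vector pairing LTR subfamilies with their
#'   internal segments.
#' @param fragmentation_prob Probability that a TE record is split into
#'   2-3 fragments (gaps 20-80 bp, shared linkage id).
#' @param tcgt_groups Sample group labels (e.g. developmental stages).
#' @param samples_per_group Transcriptome samples per group.
#' @param tcgts_per_group Planted chimeric transcripts per group.
#' @param enriched_fraction Fraction of each group's planted drivers drawn
#'   from `tcgt_subfamily`.
#' @param tcgt_subfamily The subfamily planted as the dominant TcGT driver.
#' @param n_decoys Total decoy transcripts, split evenly across the three
#'   violation modes (mono-exonic, TSS outside the LTR, junction into
#'   intergenic space).
#' @param n_background_transcripts Ordinary gene transcripts per sample.
#' @param peak_plan List: `n_peaks`, `n_replicates`, `width`,
#'   `enriched_subfamily`, `enrichment_fraction`, `jitter`,
#'   `replicate_presence`.
#' @param expr_plan List: `stages`, `replicates`, `n_maternal`, `n_zga`,
#'   `amplitude_log2`, `baseline_log2`, `noise_sd` (fraction of the
#'   amplitude), `nb_size`.
#' @param methyl_plan List: `set_size`, `mean_a`, `mean_b`,
#'   `locus_concentration`, `cpg_concentration`, `cpg_spacing` (bp),
#'   `replicates`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome = c(chr1 = 5e6, chr2 = 5e6),
                       n_genes = 120L,
                       te_plan = default_te_plan(),
                       ltr_int_pairs = c(LTR12C = "HERV9-int",
                                         LTR7 = "HERVH-int"),
                       fragmentation_prob = 0.25,
                       tcgt_groups = c("oocyte", "eightcell", "morula"),
                       samples_per_group = 3L,
                       tcgts_per_group = 10L,
                       enriched_fraction = 0.8,
                       tcgt_subfamily = "LTR12C",
                       n_decoys = 60L,
                       n_background_transcripts = 30L,
                       peak_plan = list(n_peaks = 500L, n_replicates = 3L,
                                        width = 200L,
                                        enriched_subfamily = "LTR12C",
                                        enrichment_fraction = 0.4,
                                        jitter = 20L,
                                        replicate_presence = 0.9),
                       expr_plan = list(stages = c("oocyte", "zygote",
                                                   "twocell", "fourcell",
                                                   "eightcell", "morula"),
                                        replicates = 2L,
                                        n_maternal = 30L, n_zga = 30L,
                                        amplitude_log2 = 5,
                                        baseline_log2 = log2(50),
                                        noise_sd = 0.1, nb_size = 100),
                       methyl_plan = list(set_size = 50L, mean_a = 0.7,
                                          mean_b = 0.4,
                                          locus_concentration = 10,
                                          cpg_concentration = 30,
                                          cpg_spacing = 40L,
                                          replicates = 2L)) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            fragmentation_prob >= 0, fragmentation_prob <= 1,
            enriched_fraction >= 0, enriched_fraction <= 1,
            peak_plan$enrichment_fraction >= 0,
            peak_plan$enrichment_fraction <= 1)
  structure(list(seed = as.integer(seed), genome = genome,
                 n_genes = as.integer(n_genes), te_plan = te_plan,
                 ltr_int_pairs = ltr_int_pairs,
                 fragmentation_prob = fragmentation_prob,
                 tcgt_groups = tcgt_groups,
                 samples_per_group = as.integer(samples_per_group),
                 tcgts_per_group = as.integer(tcgts_per_group),
                 enriched_fraction = enriched_fraction,
                 tcgt_subfamily = tcgt_subfamily,
                 n_decoys = as.integer(n_decoys),
                 n_background_transcripts = as.integer(n_background_transcripts),
                 peak_plan = peak_plan, expr_plan = expr_plan,
                 methyl_plan = methyl_plan),
            class = "sim_config")
}

# evaluate expr under a fixed seed without clobbering the caller's RNG
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# interval placement with kind-specific exclusion margins:
# gene-gene 150 bp, te-gene 450 bp, te-te 600 bp (keeps distinct TEs beyond
# every merge window so curation cannot fuse independent insertions)
.placer <- function(genome) {
  occ <- lapply(genome, function(len)
    data.frame(start = integer(), end = integer(), kind = character()))
  margin_for <- function(kind_new, kind_old) {
    if (kind_new == "gene" && kind_old == "gene") return(150L)
    if (kind_new == "te" && kind_old == "te") return(600L)
    450L
  }
  conflicts <- function(ch, st, en, kind) {
    o <- occ[[ch]]
    if (nrow(o) == 0) return(FALSE)
    m <- vapply(o$kind, margin_for, 1L, kind_new = kind)
    any(st <= o$end + m & en >= o$start - m)
  }
  add <- function(ch, st, en, kind) {
    occ[[ch]] <<- rbind(occ[[ch]],
                        data.frame(start = st, end = en, kind = kind))
    invisible(NULL)
  }
  place <- function(len, kind, max_tries = 500L) {
    for (i in seq_len(max_tries)) {
      ch <- sample(names(genome), 1L, prob = genome)
      hi <- genome[[ch]] - len - 1000L
      if (hi < 1000L) next
      st <- sample.int(hi, 1L) + 1000L
      en <- st + len - 1L
      if (!conflicts(ch, st, en, kind)) {
        add(ch, st, en, kind)
        return(list(chrom = ch, start = st, end = en))
      }
    }
    stop("infeasible placement: could not fit a feature of length ", len)
  }
  place_at <- function(ch, st, len, kind) {
    en <- st + len - 1L
    if (st < 1L || en > genome[[ch]] || conflicts(ch, st, en, kind)) {
      return(NULL)
    }
    add(ch, st, en, kind)
    list(chrom = ch, start = st, end = en)
  }
  list(place = place, place_at = place_at)
}

#' Simulate the toy genome annotation
#'
#' Generates gene models, the ground-truth TE catalog (including full-length
#' LTR-int-LTR elements and planted TcGT driver loci placed upstream of
#' their target genes) and a fragmented version of the catalog in which a
#' configurable fraction of records is split into linkage-tagged pieces that
#' [merge_fragments()] can reassemble exactly. All features are placed
#' without mutual overlap, with exclusion margins wider than every merge
#' window.
#'
#' @param cfg A [sim_config()].
#' @return A list with `chrom_sizes`, `genes`, `gene_exons`, `records`
#'   (pre-fragmentation catalog, full-length elements as separate LTR and
#'   internal records), `fragmented`, `curated_truth` (expected catalog
#'   after fragment reassembly, ERV assembly and solo-LTR flagging) and
#'   `tcgt_plan` (planted group/gene/driver assignments).
#' @export
simulate_annotation <- function(cfg) {
  .with_seed(cfg$seed + 101L, {
    pl <- .placer(cfg$genome)
    # --- genes: 3 exons, random strand ---
    genes <- vector("list", cfg$n_genes)
    gene_exons <- vector("list", cfg$n_genes)
    for (i in seq_len(cfg$n_genes)) {
      ex_len <- sample(150:300, 3L, replace = TRUE)
      introns <- sample(500:2000, 2L, replace = TRUE)
      total <- sum(ex_len) + sum(introns)
      pos <- pl$place(total, "gene")
      strand <- sample(c("+", "-"), 1L)
      s1 <- pos$start
      starts <- c(s1, s1 + ex_len[1L] + introns[1L],
                  s1 + ex_len[1L] + introns[1L] + ex_len[2L] + introns[2L])
      ends <- starts + ex_len - 1L
      gid <- sprintf("G%04d", i)
      rank <- if (strand == "+") 1:3 else 3:1
      gene_exons[[i]] <- data.frame(gene_id = gid, chrom = pos$chrom,
                                    start = starts, end = ends,
                                    strand = strand, exon_rank = rank,
                                    stringsAsFactors = FALSE)
      genes[[i]] <- data.frame(gene_id = gid, chrom = pos$chrom,
                               start = pos$start, end = pos$end,
                               strand = strand,
                               tss = if (strand == "+") pos$start else pos$end,
                               stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, genes)
    gene_exons <- do.call(rbind, gene_exons)

    plan <- cfg$te_plan
    other_ltr <- setdiff(plan$subfamily[plan$class == "LTR"],
                         cfg$tcgt_subfamily)
    n_enr <- round(cfg$enriched_fraction * cfg$tcgts_per_group)

    # --- planted TcGT drivers upstream of their target genes ---
    n_plant <- length(cfg$tcgt_groups) * cfg$tcgts_per_group
    if (n_plant > nrow(genes)) stop("more planted TcGTs than genes")
    gene_pool <- sample(genes$gene_id)  # fallback order for tight loci
    plant_sub <- unlist(lapply(seq_along(cfg$tcgt_groups), function(g) {
      c(rep(cfg$tcgt_subfamily, n_enr),
        sample(other_ltr, cfg$tcgts_per_group - n_enr, replace = TRUE))
    }))
    plant_group <- rep(cfg$tcgt_groups, each = cfg$tcgts_per_group)
    records <- list()
    used <- setNames(integer(nrow(plan)), plan$subfamily)
    tcgt_plan <- vector("list", n_plant)
    for (i in seq_len(n_plant)) {
      sub <- plant_sub[i]
      row <- plan[plan$subfamily == sub, ]
      len <- sample(row$min_len:row$max_len, 1L)
      placed <- NULL
      while (is.null(placed) && length(gene_pool) > 0) {
        g <- genes[genes$gene_id == gene_pool[1L], ]
        gene_pool <- gene_pool[-1L]
        for (try in 1:40) {
          gap <- sample(700:2000, 1L)
          st <- if (g$strand == "+") g$start - gap - len else g$end + gap
          placed <- pl$place_at(g$chrom, st, len, "te")
          if (!is.null(placed)) break
        }
      }
      if (is.null(placed)) stop("infeasible placement of planted drivers: ",
                                "genome too crowded")
      used[sub] <- used[sub] + 1L
      lid <- sprintf("%s_%04d", sub, used[sub])
      records[[length(records) + 1L]] <- data.frame(
        chrom = placed$chrom, start = placed$start, end = placed$end,
        strand = g$strand, subfamily = sub, family = row$family,
        class = row$class, locus_id = lid, solo_truth = TRUE,
        element_id = NA_character_, stringsAsFactors = FALSE)
      tcgt_plan[[i]] <- data.frame(group = plant_group[i],
                                   gene_id = g$gene_id, locus_id = lid,
                                   subfamily = sub, stringsAsFactors = FALSE)
    }
    tcgt_plan <- do.call(rbind, tcgt_plan)

    # --- remaining solo loci ---
    for (r in seq_len(nrow(plan))) {
      sub <- plan$subfamily[r]
      n_left <- plan$n_solo[r] - used[sub]
      for (j in seq_len(max(0L, n_left))) {
        len <- sample(plan$min_len[r]:plan$max_len[r], 1L)
        pos <- pl$place(len, "te")
        used[sub] <- used[sub] + 1L
        records[[length(records) + 1L]] <- data.frame(
          chrom = pos$chrom, start = pos$start, end = pos$end,
          strand = sample(c("+", "-"), 1L), subfamily = sub,
          family = plan$family[r], class = plan$class[r],
          locus_id = sprintf("%s_%04d", sub, used[sub]),
          solo_truth = plan$class[r] == "LTR",
          element_id = NA_character_, stringsAsFactors = FALSE)
      }
    }

    # --- full-length elements: LTR + internal + LTR ---
    n_elem <- 0L
    for (r in which(plan$n_full > 0)) {
      sub <- plan$subfamily[r]
      int_sub <- cfg$ltr_int_pairs[[sub]]
      if (is.null(int_sub)) stop("no internal pairing for ", sub)
      for (j in seq_len(plan$n_full[r])) {
        n_elem <- n_elem + 1L
        ltr_len <- sample(plan$min_len[r]:plan$max_len[r], 2L, replace = TRUE)
        int_len <- sample(5000:7000, 1L)
        gaps <- sample(20:100, 2L, replace = TRUE)
        total <- sum(ltr_len) + int_len + sum(gaps)
        pos <- pl$place(total, "te")
        strand <- sample(c("+", "-"), 1L)
        eid <- sprintf("ERVelem_%03d", n_elem)
        s1 <- pos$start
        comp <- data.frame(
          chrom = pos$chrom,
          start = c(s1, s1 + ltr_len[1L] + gaps[1L],
                    s1 + ltr_len[1L] + gaps[1L] + int_len + gaps[2L]),
          end = c(s1 + ltr_len[1L] - 1L,
                  s1 + ltr_len[1L] + gaps[1L] + int_len - 1L,
                  s1 + ltr_len[1L] + gaps[1L] + int_len + gaps[2L] +
                    ltr_len[2L] - 1L),
          strand = strand,
          subfamily = c(sub, int_sub, sub),
          family = plan$family[r], class = "LTR",
          locus_id = sprintf("%s_%s", eid, c("ltr5", "int", "ltr3")),
          solo_truth = FALSE, element_id = eid, stringsAsFactors = FALSE)
        records[[length(records) + 1L]] <- comp
      }
    }
    rec <- do.call(rbind, records)

    # --- expected curated catalog (ERVs assembled, solo flags set) ---
    cur <- list()
    for (i in which(is.na(rec$element_id))) {
      cur[[length(cur) + 1L]] <- data.frame(
        chrom = rec$chrom[i], start = rec$start[i], end = rec$end[i],
        strand = rec$strand[i], subfamily = rec$subfamily[i],
        family = rec$family[i], class = rec$class[i],
        locus_id = rec$locus_id[i], is_solo_ltr = rec$solo_truth[i],
        merged_from = rec$locus_id[i], stringsAsFactors = FALSE)
    }
    for (eid in unique(rec$element_id[!is.na(rec$element_id)])) {
      mem <- rec[!is.na(rec$element_id) & rec$element_id == eid, ]
      int <- mem[grepl("-int$", mem$subfamily), ]
      cur[[length(cur) + 1L]] <- data.frame(
        chrom = mem$chrom[1L], start = min(mem$start), end = max(mem$end),
        strand = mem$strand[1L], subfamily = int$subfamily[1L],
        family = int$family[1L], class = "LTR",
        locus_id = int$locus_id[1L], is_solo_ltr = FALSE,
        merged_from = paste(mem$locus_id[order(mem$start)], collapse = ","),
        stringsAsFactors = FALSE)
    }
    cur <- do.call(rbind, cur)
    curated_truth <- te_catalog(cur$chrom, cur$start, cur$end, cur$strand,
                                cur$subfamily, cur$family, cur$class,
                                cur$locus_id, NA_character_,
                                cur$is_solo_ltr, cur$merged_from)

    records_gr <- te_catalog(rec$chrom, rec$start, rec$end, rec$strand,
                             rec$subfamily, rec$family, rec$class,
                             rec$locus_id)
    fragmented <- .fragment_catalog(records_gr, cfg$fragmentation_prob)

    list(chrom_sizes = cfg$genome, genes = genes, gene_exons = gene_exons,
         records = records_gr, fragmented = fragmented,
         curated_truth = curated_truth, tcgt_plan = tcgt_plan)
  })
}

# split records into 2-3 linkage-tagged fragments with 20-80 bp gaps;
# fragment spans tile the original span so reassembly is exact
.fragment_catalog <- function(records, prob) {
  if (prob <= 0 || length(records) == 0) return(records)
  df <- .catalog_df(records)
  out <- list()
  for (i in seq_len(nrow(df))) {
    len <- df$end[i] - df$start[i] + 1L
    if (runif(1) >= prob || len < 300L) {
      out[[length(out) + 1L]] <- df[i, , drop = FALSE]
      next
    }
    n_pieces <- sample(2:3, 1L)
    gaps <- sample(20:80, n_pieces - 1L, replace = TRUE)
    body <- len - sum(gaps)
    cuts <- sort(sample.int(body - n_pieces, n_pieces - 1L))
    piece_len <- diff(c(0L, cuts, body - n_pieces)) + 1L
    st <- df$start[i]
    for (p in seq_len(n_pieces)) {
      en <- st + piece_len[p] - 1L
      rec <- df[i, , drop = FALSE]
      rec$start <- st; rec$end <- en
      rec$locus_id <- sprintf("%s_f%d", df$locus_id[i], p)
      rec$linkage_id <- df$locus_id[i]
      rec$merged_from <- rec$locus_id
      out[[length(out) + 1L]] <- rec
      if (p < n_pieces) st <- en + gaps[p] + 1L
    }
    # last piece must end exactly at the original end
    out[[length(out)]]$end <- df$end[i]
  }
  .catalog_from_df(do.call(rbind, out))
}

#' Simulate per-sample transcriptomes with planted TcGTs
#'
#' Each planted TcGT becomes a two-exon transcript whose TSS lies inside its
#' driver LTR and whose second exon coincides with the target gene's first
#' annotated exon (a genuine splice into the gene). Decoy transcripts each
#' violate exactly one calling predicate: mono-exonic inside an LTR, TSS
#' just outside an LTR with a valid junction into a gene, or TSS inside an
#' LTR with the junction landing in intergenic space. Background transcripts
#' are plain copies of gene models.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return A list with `transcripts` (exon table), `samples` (sample/group
#'   table), `groups` (named vector), `truth` (planted TcGTs with emitting
#'   samples) and `decoys`.
#' @export
simulate_transcriptomes <- function(cfg, ann) {
  .with_seed(cfg$seed + 202L, {
    samples <- do.call(rbind, lapply(cfg$tcgt_groups, function(g)
      data.frame(sample_id = sprintf("%s_s%d", g,
                                     seq_len(cfg$samples_per_group)),
                 group = g, stringsAsFactors = FALSE)))
    groups <- setNames(samples$group, samples$sample_id)
    cat_df <- .catalog_df(ann$curated_truth)
    gene_first_exon <- function(gid) {
      ex <- ann$gene_exons[ann$gene_exons$gene_id == gid, ]
      ex[ex$exon_rank == 1L, ]
    }
    exons <- list()
    emit <- function(tid, sid, chrom, starts, ends, strand) {
      exons[[length(exons) + 1L]] <<- data.frame(
        transcript_id = tid, sample_id = sid, chrom = chrom,
        start = starts, end = ends, strand = strand,
        stringsAsFactors = FALSE)
    }
    chimeric_exons <- function(locus, gid, shift = 0L) {
      # first exon anchored inside the driver, second = gene's first exon
      te <- cat_df[cat_df$locus_id == locus, ]
      fe <- gene_first_exon(gid)
      off <- sample(10:100, 1L)
      if (fe$strand == "+") {
        tss <- te$start + off + shift
        list(chrom = te$chrom, starts = c(tss, fe$start),
             ends = c(tss + 150L, fe$end), strand = "+")
      } else {
        tss <- te$end - off + shift
        list(chrom = te$chrom, starts = c(fe$start, tss - 150L),
             ends = c(fe$end, tss), strand = "-")
      }
    }
    # --- planted TcGTs ---
    truth <- ann$tcgt_plan
    truth$samples <- vapply(seq_len(nrow(truth)), function(i) {
      grp_samples <- samples$sample_id[samples$group == truth$group[i]]
      n_emit <- if (length(grp_samples) <= 2L) length(grp_samples)
                else sample(2:length(grp_samples), 1L)
      chosen <- sort(sample(grp_samples, n_emit))
      for (sid in chosen) {
        ce <- chimeric_exons(truth$locus_id[i], truth$gene_id[i])
        emit(sprintf("tcgt_%s_%s", truth$locus_id[i], sid), sid,
             ce$chrom, ce$starts, ce$ends, ce$strand)
      }
      paste(chosen, collapse = ",")
    }, "")
    # --- background gene transcripts ---
    for (sid in samples$sample_id) {
      for (gid in sample(ann$genes$gene_id, cfg$n_background_transcripts)) {
        ex <- ann$gene_exons[ann$gene_exons$gene_id == gid, ]
        emit(sprintf("bg_%s_%s", gid, sid), sid, ex$chrom[1L],
             ex$start, ex$end, ex$strand[1L])
      }
    }
    # --- decoys, each violating exactly one predicate ---
    n_per <- cfg$n_decoys %/% 3L
    n_mono <- cfg$n_decoys - 2L * n_per
    solo <- cat_df[cat_df$is_solo_ltr & cat_df$end - cat_df$start >= 300L, ]
    decoys <- list()
    for (d in seq_len(n_mono)) {  # mono-exonic inside an LTR
      te <- solo[sample.int(nrow(solo), 1L), ]
      sid <- sample(samples$sample_id, 1L)
      tid <- sprintf("decoy_mono_%03d", d)
      emit(tid, sid, te$chrom, te$start + 10L, te$start + 200L, te$strand)
      decoys[[length(decoys) + 1L]] <- data.frame(
        transcript_id = tid, mode = "mono_exonic", stringsAsFactors = FALSE)
    }
    plan_cycle <- ann$tcgt_plan[rep(seq_len(nrow(ann$tcgt_plan)),
                                    length.out = n_per), ]
    for (d in seq_len(n_per)) {  # TSS just outside the LTR, junction valid
      pr <- plan_cycle[d, ]
      te <- cat_df[cat_df$locus_id == pr$locus_id, ]
      fe <- gene_first_exon(pr$gene_id)
      sid <- sample(samples$sample_id, 1L)
      tid <- sprintf("decoy_outside_%03d", d)
      if (fe$strand == "+") {
        emit(tid, sid, te$chrom, c(te$start - 200L, fe$start),
             c(te$start - 50L, fe$end), "+")
      } else {
        emit(tid, sid, te$chrom, c(fe$start, te$end + 50L),
             c(fe$end, te$end + 200L), "-")
      }
      decoys[[length(decoys) + 1L]] <- data.frame(
        transcript_id = tid, mode = "tss_outside", stringsAsFactors = FALSE)
    }
    for (d in seq_len(n_per)) {  # TSS inside, junction into intergenic space
      te <- solo[sample.int(nrow(solo), 1L), ]
      sid <- sample(samples$sample_id, 1L)
      tid <- sprintf("decoy_intergenic_%03d", d)
      if (te$strand == "+") {
        emit(tid, sid, te$chrom, c(te$start + 10L, te$end + 250L),
             c(te$start + 160L, te$end + 400L), "+")
      } else {
        emit(tid, sid, te$chrom, c(te$start - 400L, te$end - 160L),
             c(te$start - 250L, te$end - 10L), "-")
      }
      decoys[[length(decoys) + 1L]] <- data.frame(
        transcript_id = tid, mode = "intergenic_junction",
        stringsAsFactors = FALSE)
    }
    list(transcripts = do.call(rbind, exons), samples = samples,
         groups = groups, truth = truth, decoys = do.call(rbind, decoys))
  })
}

#' Simulate replicate ChIP peak sets with a planted subfamily enrichment
#'
#' A configurable fraction of peaks is placed entirely inside loci of the
#' enriched subfamily (guaranteeing the >50% overlap rule); the remainder
#' is placed uniformly on the genome. Replicates carry the same peaks
#' jittered by a few bases, each peak present in a replicate with
#' probability `replicate_presence`.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return A list with `base` (the replicate-free peak set as a `GRanges`
#'   with an `enriched` flag), `replicates` (list of `GRanges`) and
#'   `truth`.
#' @export
simulate_peaks <- function(cfg, ann) {
  .with_seed(cfg$seed + 303L, {
    pp <- cfg$peak_plan
    cat_df <- .catalog_df(ann$curated_truth)
    targets <- cat_df[cat_df$subfamily == pp$enriched_subfamily &
                        (cat_df$end - cat_df$start + 1L) > pp$width + 20L, ]
    if (nrow(targets) == 0 && pp$enrichment_fraction > 0) {
      stop("no loci of the enriched subfamily can hold a peak")
    }
    n_enr <- round(pp$enrichment_fraction * pp$n_peaks)
    chrom <- character(pp$n_peaks)
    start <- integer(pp$n_peaks)
    if (n_enr > 0) {
      ti <- sample.int(nrow(targets), n_enr, replace = TRUE)
      lens <- targets$end[ti] - targets$start[ti] + 1L
      off <- vapply(lens, function(l)
        sample.int(l - pp$width + 1L, 1L) - 1L, 1L)
      chrom[seq_len(n_enr)] <- targets$chrom[ti]
      start[seq_len(n_enr)] <- targets$start[ti] + off
    }
    n_unif <- pp$n_peaks - n_enr
    if (n_unif > 0) {
      idx <- n_enr + seq_len(n_unif)
      chrom[idx] <- sample(names(cfg$genome), n_unif, replace = TRUE,
                           prob = cfg$genome)
      start[idx] <- vapply(chrom[idx], function(ch)
        sample.int(cfg$genome[[ch]] - pp$width, 1L), 1L)
    }
    base <- GRanges(chrom, IRanges(start, width = pp$width))
    mcols(base)$enriched <- seq_len(pp$n_peaks) <= n_enr
    replicates <- lapply(seq_len(pp$n_replicates), function(r) {
      present <- runif(pp$n_peaks) < pp$replicate_presence
      shift <- as.integer(round(runif(pp$n_peaks, -pp$jitter, pp$jitter)))
      gr <- GRanges(chrom[present],
                    IRanges(pmax(1L, start[present] + shift[present]),
                            width = pp$width))
      sort(gr)
    })
    list(base = base, replicates = replicates,
         truth = list(enriched_subfamily = pp$enriched_subfamily,
                      enrichment_fraction = pp$enrichment_fraction,
                      n_enriched = n_enr))
  })
}

#' Simulate a gene + TE-locus count matrix with temporal patterns
#'
#' TE loci are split into a maternal pattern (expressed in the first two
#' stages, silent after) and a ZGA pattern (silent early, expressed in the
#' last two stages). Counts are negative binomial around
#' `2^(baseline + amplitude * template + noise)` scaled by a per-sample
#' depth factor; `noise_sd` is expressed as a fraction of the log2
#' amplitude. Gene rows with stage-independent means are included so that
#' TMM normalization on gene counts is exercised.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return A list with `counts`, `feature_kind`, `samples` (stage/replicate
#'   table) and `truth_labels` (named `"maternal"`/`"zga"` vector).
#' @export
simulate_expression <- function(cfg, ann) {
  .with_seed(cfg$seed + 404L, {
    ep <- cfg$expr_plan
    cat_df <- .catalog_df(ann$curated_truth)
    ltr <- cat_df[cat_df$class == "LTR" & cat_df$is_solo_ltr, ]
    pref <- ltr[order(ltr$subfamily != cfg$tcgt_subfamily, ltr$locus_id), ]
    n_loci <- ep$n_maternal + ep$n_zga
    if (n_loci > nrow(pref)) stop("not enough LTR loci for the expression plan")
    loci <- pref$locus_id[seq_len(n_loci)]
    labels <- sample(rep(c("maternal", "zga"), c(ep$n_maternal, ep$n_zga)))
    names(labels) <- loci
    n_stage <- length(ep$stages)
    samples <- data.frame(
      sample_id = as.vector(t(outer(ep$stages, seq_len(ep$replicates),
                                    function(s, r) sprintf("%s_r%d", s, r)))),
      stage = rep(ep$stages, each = ep$replicates),
      replicate = rep(seq_len(ep$replicates), n_stage),
      stringsAsFactors = FALSE)
    maternal_on <- samples$stage %in% ep$stages[1:2]
    zga_on <- samples$stage %in% ep$stages[(n_stage - 1L):n_stage]
    depth <- runif(nrow(samples), 0.7, 1.3)
    te_counts <- t(vapply(loci, function(l) {
      tmpl <- if (labels[[l]] == "maternal") maternal_on else zga_on
      lmu <- ep$baseline_log2 + ep$amplitude_log2 * as.numeric(tmpl) +
        rnorm(nrow(samples), 0, ep$noise_sd * ep$amplitude_log2)
      rnbinom(nrow(samples), mu = 2^lmu * depth, size = ep$nb_size)
    }, numeric(nrow(samples))))
    gene_mu <- rlnorm(nrow(ann$genes), meanlog = log(200), sdlog = 0.7)
    gene_counts <- t(vapply(seq_len(nrow(ann$genes)), function(i)
      rnbinom(nrow(samples), mu = gene_mu[i] * depth, size = ep$nb_size),
      numeric(nrow(samples))))
    rownames(gene_counts) <- ann$genes$gene_id
    rownames(te_counts) <- loci
    counts <- rbind(gene_counts, te_counts)
    colnames(counts) <- samples$sample_id
    feature_kind <- rep(c("gene", "te_locus"),
                        c(nrow(gene_counts), nrow(te_counts)))
    list(counts = counts, feature_kind = feature_kind, samples = samples,
         truth_labels = labels)
  })
}

#' Simulate per-CpG methylation with a planted set difference
#'
#' Two disjoint sets of solo-LTR loci receive locus-level methylation drawn
#' from Beta distributions centered at `mean_a` and `mean_b`; individual
#' CpGs (one every `cpg_spacing` bp, per replicate) scatter around their
#' locus level with concentration `cpg_concentration`.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return A list with `calls` (CpG table), `truth` (locus sets, planted
#'   means, per-locus true levels).
#' @export
simulate_methylation <- function(cfg, ann) {
  .with_seed(cfg$seed + 505L, {
    mp <- cfg$methyl_plan
    empty <- data.frame(chrom = character(), pos = integer(),
                        meth_level = numeric(), sample_id = character(),
                        stringsAsFactors = FALSE)
    if (mp$set_size <= 0 || is.na(mp$cpg_spacing) || mp$cpg_spacing <= 0) {
      return(list(calls = empty,
                  truth = list(set_a = character(), set_b = character(),
                               mean_a = mp$mean_a, mean_b = mp$mean_b,
                               locus_levels = numeric())))
    }
    cat_df <- .catalog_df(ann$curated_truth)
    solo <- cat_df[cat_df$is_solo_ltr, ]
    n_need <- 2L * mp$set_size
    if (n_need > nrow(solo)) stop("not enough solo LTR loci for methylation sets")
    chosen <- solo[sample.int(nrow(solo), n_need), ]
    set_a <- chosen$locus_id[seq_len(mp$set_size)]
    set_b <- chosen$locus_id[mp$set_size + seq_len(mp$set_size)]
    mu <- ifelse(chosen$locus_id %in% set_a, mp$mean_a, mp$mean_b)
    lvl <- rbeta(n_need, mu * mp$locus_concentration,
                 (1 - mu) * mp$locus_concentration)
    # keep levels off the exact boundaries so per-CpG Beta draws are proper
    lvl <- pmin(pmax(lvl, 0.01), 0.99)
    names(lvl) <- chosen$locus_id
    sids <- sprintf("pgc_r%d", seq_len(mp$replicates))
    calls <- list()
    for (i in seq_len(n_need)) {
      pos <- seq(chosen$start[i] + 10L, chosen$end[i] - 10L,
                 by = mp$cpg_spacing)
      if (length(pos) == 0) next
      for (sid in sids) {
        meth <- rbeta(length(pos), lvl[i] * mp$cpg_concentration,
                      (1 - lvl[i]) * mp$cpg_concentration)
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = chosen$chrom[i], pos = pos, meth_level = meth,
          sample_id = sid, stringsAsFactors = FALSE)
      }
    }
    list(calls = if (length(calls)) do.call(rbind, calls) else empty,
         truth = list(set_a = set_a, set_b = set_b, mean_a = mp$mean_a,
                      mean_b = mp$mean_b, locus_levels = lvl,
                      replicates = sids))
  })
}

#' Simulate the complete toy dataset
#'
#' Runs every generator stage and bundles the outputs with a ground-truth
#' record sufficient to score every pipeline stage.
#'
#' @param cfg A [sim_config()].
#' @return A list with `annotation`, `transcriptomes`, `peaks`,
#'   `expression`, `methylation`, `config` and `ground_truth`.
#' @export
simulate_dataset <- function(cfg) {
  ann <- simulate_annotation(cfg)
  tr <- simulate_transcriptomes(cfg, ann)
  pk <- simulate_peaks(cfg, ann)
  ex <- simulate_expression(cfg, ann)
  me <- simulate_methylation(cfg, ann)
  list(annotation = ann, transcriptomes = tr, peaks = pk, expression = ex,
       methylation = me, config = cfg,
       ground_truth = list(
         curated_catalog = ann$curated_truth,
         planted_tcgts = tr$truth,
         decoys = tr$decoys,
         enriched_peak_subfamily = pk$truth$enriched_subfamily,
         cluster_labels = ex$truth_labels,
         methylation = me$truth))
}
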