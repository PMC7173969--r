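#' Simulate a genome under a structured-coalescent demography
#'
#' Generates phased haplotypes, the true ancestral allele at every site (the
#' REF allele: mutations are placed on the genealogy under infinite sites),
#' and the full record of pairwise coalescence times needed for relative
#' cross-coalescence rates. Each scaffold is cut into `block_bp` blocks with
#' one independent genealogy per block (an independent-locus approximation
#' of recombination); within a block the standard structured coalescent runs
#' backward through the demography's resize/pulse/merge events. Mutations
#' are Poisson on branches with rate `mu` per site per generation; duplicate
#' positions within a block are discarded (infinite-sites at the block
#' scale).
#'
#' @param params a [demography_params()] (or [neutral_demography()]) object.
#' @param mutations generate mutations and haplotypes (disable when only
#'   coalescence times are needed; much faster with deep outgroups).
#' @param seed RNG seed; the same seed reproduces the simulation exactly.
#' @return list of class `sim_bundle`: `hm` (the [haplotype_matrix()]; NULL
#'   when `mutations = FALSE`), `popmap`, `coal` (list of `time`, `counts`
#'   matrix of coalescing pair counts, `classes` population-pair table),
#'   `truth` (parameters and any injected sweep), `params`.
#' @export
simulate_demography <- function(params, mutations = TRUE, seed = NULL) {
  stopifnot(inherits(params, "demography_params"))
  if (!is.null(seed)) set.seed(seed)
  pops <- params$pops
  npop <- length(pops)
  n_hap <- 2L * params$samples[pops]
  ntips <- sum(n_hap)
  tip_pop <- rep(seq_len(npop), n_hap)
  ev <- params$events[order(vapply(params$events, `[[`, numeric(1L), "time"))]
  # class layout: unordered population pairs in upper.tri(diag) column order
  ij <- which(upper.tri(matrix(0L, npop, npop), diag = TRUE), arr.ind = TRUE)
  nclass <- nrow(ij)
  classes <- data.frame(a = pops[ij[, 1L]], b = pops[ij[, 2L]])
  ut <- upper.tri(matrix(0L, npop, npop), diag = TRUE)

  scaffold_names <- sprintf("scaffold_%d", seq_len(params$n_scaffolds))
  blocks_per_sc <- ceiling(params$scaffold_bp / params$block_bp)
  n_blocks <- params$n_scaffolds * blocks_per_sc
  coal_time <- vector("list", n_blocks)
  coal_counts <- vector("list", n_blocks)
  block_alle <- if (mutations) vector("list", n_blocks)
  block_pos <- if (mutations) vector("list", n_blocks)
  block_sc <- if (mutations) character(n_blocks)

  bi <- 0L
  for (sc in seq_len(params$n_scaffolds)) {
    for (bk in seq_len(blocks_per_sc)) {
      bi <- bi + 1L
      b_start <- (bk - 1L) * params$block_bp
      b_len <- min(params$block_bp, params$scaffold_bp - b_start)
      blk <- sim_block(params, ev, npop, ntips, tip_pop, ut, nclass,
                       b_len, mutations)
      coal_time[[bi]] <- blk$coal_time
      coal_counts[[bi]] <- blk$coal_counts
      if (mutations) {
        block_alle[[bi]] <- blk$alleles
        block_pos[[bi]] <- blk$pos + b_start
        block_sc[bi] <- scaffold_names[sc]
      }
    }
  }
  coal <- list(time = unlist(coal_time),
               counts = do.call(rbind, coal_counts),
               classes = classes)
  sample_ids <- unlist(lapply(pops, function(p)
    sprintf("%s_%d", p, seq_len(params$samples[[p]]))))
  popmap <- data.frame(
    sample_id = sample_ids,
    population = rep(pops, params$samples[pops]),
    phenotype_class = rep(unname(params$phenotype_class), params$samples[pops]),
    distance_code = rep(unname(params$distance_code), params$samples[pops]))
  hm <- NULL
  if (mutations) {
    S_tot <- sum(vapply(block_pos, length, integer(1L)))
    alle <- matrix(0L, nrow = ntips, ncol = S_tot)
    positions <- integer(S_tot)
    scaff <- character(S_tot)
    at <- 0L
    for (b in seq_len(n_blocks)) {
      nb <- length(block_pos[[b]])
      if (!nb) next
      alle[, at + seq_len(nb)] <- block_alle[[b]]
      positions[at + seq_len(nb)] <- block_pos[[b]]
      scaff[at + seq_len(nb)] <- block_sc[b]
      at <- at + nb
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, S_tot, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))
    hm <- haplotype_matrix(alle, positions, scaff, ref = ref, alt = alt,
                           samples = sample_ids,
                           scaffold_lengths = stats::setNames(
                             rep(params$scaffold_bp, params$n_scaffolds),
                             scaffold_names))
  }
  structure(list(hm = hm, popmap = popmap, coal = coal,
                 truth = list(split_time = params$split_time,
                              pulse_time = params$pulse_time,
                              pulse_frac = params$pulse_frac,
                              t_out = params$t_out, sweep = NULL),
                 params = params),
            class = "sim_bundle")
}

# one block: structured coalescent + optional mutations
sim_block <- function(params, ev, npop, ntips, tip_pop, ut, nclass,
                      b_len, mutations) {
  max_nodes <- 2L * ntips - 1L
  node_time <- numeric(max_nodes)
  counts <- matrix(0L, max_nodes, npop)
  counts[cbind(seq_len(ntips), tip_pop)] <- 1L
  tipsets <- if (mutations) c(as.list(seq_len(ntips)),
                              vector("list", ntips - 1L))
  edge_child <- integer(2L * (ntips - 1L))
  edge_len <- numeric(2L * (ntips - 1L))
  n_edge <- 0L
  ncoal <- ntips - 1L
  c_time <- numeric(ncoal)
  c_counts <- matrix(0, ncoal, nclass)
  act <- seq_len(ntips)
  act_pop <- tip_pop
  N_cur <- params$N0[params$pops]
  t <- 0
  ev_i <- 1L
  nev <- length(ev)
  next_node <- ntips
  ci <- 0L
  while (length(act) > 1L) {
    k <- tabulate(act_pop, npop)
    rate_p <- k * (k - 1) / 2 / (2 * N_cur)
    R <- sum(rate_p)
    t_ev <- if (ev_i <= nev) ev[[ev_i]]$time else Inf
    dt <- if (R > 0) stats::rexp(1L, R) else Inf
    if (t + dt >= t_ev) {
      t <- t_ev
      e <- ev[[ev_i]]
      ev_i <- ev_i + 1L
      if (e$type == "resize") {
        N_cur[[e$pop]] <- e$N
      } else if (e$type == "merge") {
        act_pop[act_pop == match(e$from, params$pops)] <-
          match(e$to, params$pops)
      } else if (e$type == "pulse") {
        from_i <- match(e$from, params$pops)
        to_i <- match(e$to, params$pops)
        idx <- which(act_pop == from_i)
        if (length(idx)) {
          mv <- idx[stats::runif(length(idx)) < e$frac]
          act_pop[mv] <- to_i
        }
      }
      next
    }
    t <- t + dt
    p <- sample.int(npop, 1L, prob = rate_p)
    in_p <- which(act_pop == p)
    pick <- in_p[sample.int(length(in_p), 2L)]
    i <- act[pick[1L]]
    j <- act[pick[2L]]
    next_node <- next_node + 1L
    node_time[next_node] <- t
    counts[next_node, ] <- counts[i, ] + counts[j, ]
    if (mutations) {
      tipsets[[next_node]] <- c(tipsets[[i]], tipsets[[j]])
      edge_child[n_edge + 1L] <- i
      edge_child[n_edge + 2L] <- j
      edge_len[n_edge + 1L] <- t - node_time[i]
      edge_len[n_edge + 2L] <- t - node_time[j]
      n_edge <- n_edge + 2L
    }
    ci <- ci + 1L
    c_time[ci] <- t
    M <- tcrossprod(counts[i, ], counts[j, ])
    sym <- M + t(M)
    diag(sym) <- diag(M)
    c_counts[ci, ] <- sym[ut]
    act <- c(act[-pick], next_node)
    act_pop <- c(act_pop[-pick], p)
  }
  out <- list(coal_time = c_time, coal_counts = c_counts)
  if (mutations) {
    nm <- stats::rpois(n_edge, params$mu * b_len * edge_len[seq_len(n_edge)])
    tot <- sum(nm)
    if (tot == 0L) {
      out$alleles <- matrix(0L, ntips, 0L)
      out$pos <- integer(0)
      return(out)
    }
    mut_edge <- rep.int(seq_len(n_edge), nm)
    pos <- sample.int(b_len, tot, replace = TRUE)
    keep <- !duplicated(pos)
    mut_edge <- mut_edge[keep]
    pos <- pos[keep]
    o <- order(pos)
    mut_edge <- mut_edge[o]
    pos <- pos[o]
    A <- matrix(0L, ntips, length(pos))
    for (m in seq_along(pos))
      A[tipsets[[edge_child[mut_edge[m]]]], m] <- 1L
    out$alleles <- A
    out$pos <- pos
  }
  out
}

#' Export a simulation bundle to disk
#'
#' Writes the phased VCF, the population map TSV, the true-ancestral table
#' TSV, the truth record JSON and the coalescence-record table TSV.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$hm))
    write_vcf(bundle$hm, file.path(dir, "simulated.vcf"))
  write_population_map(bundle$popmap, file.path(dir, "population_map.tsv"))
  if (!is.null(bundle$hm))
    write_ancestral_table(ancestral_from_truth(bundle),
                          file.path(dir, "ancestral.tsv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  ct <- data.frame(time = bundle$coal$time, bundle$coal$counts)
  names(ct)[-1L] <- paste(bundle$coal$classes$a, bundle$coal$classes$b,
                          sep = "|")
  utils::write.table(ct, file.path(dir, "coalescence_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Mean per-site divergence between ingroup haplotypes and the outgroup
#' consensus
#'
#' The outgroup consensus takes the majority allele among the species'
#' haplotypes at each site; divergence is the mean, over ingroup haplotypes,
#' of the fraction of sites (per bp of simulated sequence) at which the
#' haplotype and the consensus differ.
#'
#' @param bundle a `sim_bundle` simulated with an outgroup and mutations.
#' @param species outgroup population used for the consensus (default
#'   `"out1"`).
#' @return scalar divergence (substitutions per site).
#' @export
outgroup_divergence <- function(bundle, species = "out1") {
  hm <- bundle$hm
  if (is.null(hm)) stop("bundle was simulated without mutations")
  if (!species %in% bundle$popmap$population) stop("no such outgroup: ", species)
  out_rows <- population_rows(hm, bundle$popmap, pops = species,
                              drop_outgroup = FALSE)[[1L]]
  ing <- bundle$popmap$sample_id[bundle$popmap$phenotype_class != "outgroup"]
  ing_rows <- hap_rows(hm, ing)
  cons <- as.integer(colMeans(hm$alleles[out_rows, , drop = FALSE]) > 0.5)
  L <- bundle$params$n_scaffolds * bundle$params$scaffold_bp
  diffs <- abs(hm$alleles[ing_rows, , drop = FALSE] -
                 matrix(cons, length(ing_rows), n_sites(hm), byrow = TRUE))
  mean(rowSums(diffs) / L)
}
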