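# Ground-truth generators: mitovirus-like genomes with a controlled RdRp
# length, %UGA-for-Trp and an optionally embedded N-terminal motif; labelled
# reference protein sets; and metatranscriptome library/site metadata with
# planted community gradients and a planted co-occurrence correlation.
# Defaults mirror the study conditions of the screen: large-class RdRps
# average 1,036 aa (986-1,134) with rare UGA (theta 0.014), normal-class
# RdRps average 761 aa (556-1,136), an 8-vs-6 class split, and 184
# libraries for the community simulations.

.syn_codons <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      code <- genetic_code(4L)
      by_aa <- split(names(code), unname(code))
      by_aa[["*"]] <- NULL
      tab <<- by_aa
    }
    tab
  }
})

.rand_protein <- function(len, trp_density) {
  p_w <- trp_density / 100
  prob <- stats::setNames(rep((1 - p_w) / 19, 20), AA20)
  prob["W"] <- p_w
  aa <- sample(AA20, len, replace = TRUE, prob = prob)
  aa[1] <- "M"
  aa
}

.mutate_protein <- function(aa, rate) {
  hit <- which(stats::runif(length(aa)) < rate)
  hit <- hit[hit > 1L]  # keep the initiator Met
  if (length(hit) > 0L) {
    repl <- sample(setdiff(AA20, "W"), length(hit), replace = TRUE)
    aa[hit] <- repl
  }
  aa
}

# codons for an aa vector under code table 4; Trp drawn UGA with prob theta
.codons_for <- function(aa, theta_uga) {
  syn <- .syn_codons()
  codons <- character(length(aa))
  for (a in unique(aa)) {
    pos <- which(aa == a)
    if (a == "W") {
      codons[pos] <- ifelse(stats::runif(length(pos)) < theta_uga,
                            "UGA", "UGG")
    } else {
      cands <- syn[[a]]
      codons[pos] <- cands[sample.int(length(cands), length(pos),
                                      replace = TRUE)]
    }
  }
  codons
}

# UTR nucleotides containing no AUG (or reverse-strand CAU) trigram, so the
# planted start is the first in-frame AUG in every frame
.rand_utr <- function(len) {
  if (len <= 0L) return("")
  nt <- character(len)
  bases <- c("A", "C", "G", "U")
  for (i in seq_len(len)) {
    repeat {
      nt[i] <- sample(bases, 1L)
      if (i < 3L) break
      tri <- paste0(nt[i - 2L], nt[i - 1L], nt[i])
      if (tri != "AUG" && tri != "CAU") break
    }
  }
  paste(nt, collapse = "")
}

.trunc_norm_len <- function(n, mean, sd, range) {
  len <- round(stats::rnorm(n, mean, sd))
  as.integer(pmin(pmax(len, range[1]), range[2]))
}

#' Generate a seed alignment for the N-terminal motif
#'
#' A random consensus block plus mutated copies, emulating the conserved
#' 53-58 aa N-terminal block shared by large-duamitovirus RdRps.
#'
#' @param width Motif width in aa (default 55).
#' @param n_seqs Number of aligned seed rows (default 8).
#' @param mutation_rate Per-position substitution probability per row
#'   (default 0.15, i.e. rows ~85% identical to the consensus).
#' @param seed Integer seed.
#' @return List: `alignment` (named character vector of gap-free aligned
#'   rows) and `consensus` (the consensus string).
#' @export
gen_motif_seed <- function(width = 55L, n_seqs = 8L, mutation_rate = 0.15,
                           seed = 1L) {
  .with_seed(seed, {
    consensus <- sample(setdiff(AA20, "W"), width, replace = TRUE)
    rows <- vapply(seq_len(n_seqs), function(i) {
      aa <- consensus
      hit <- which(stats::runif(width) < mutation_rate)
      if (length(hit) > 0L) {
        aa[hit] <- sample(setdiff(AA20, "W"), length(hit), replace = TRUE)
      }
      paste(aa, collapse = "")
    }, character(1))
    names(rows) <- sprintf("seed%02d", seq_len(n_seqs))
    list(alignment = rows, consensus = paste(consensus, collapse = ""))
  })
}

#' Generate mitovirus-like genomes with known ground truth
#'
#' Each genome is 5'UTR + AUG + a codon sequence encoding a random protein
#' (the motif embedded within the first 100 aa for the large class) + a
#' UAA/UAG stop + 3'UTR. Trp codons are drawn UGA with the class's
#' `theta_uga`, else UGG; UTRs contain no AUG trigram, so the planted ORF is
#' the first-AUG ORF of its frame and (with overwhelming probability) the
#' unique longest ORF of the genome.
#'
#' @param n_large,n_normal Class sizes (defaults 8 and 6).
#' @param motif Amino-acid string embedded in large-class RdRps (e.g. the
#'   consensus from [gen_motif_seed()]); must not contain W.
#' @param large_len_mean,large_len_sd,large_len_range Large-class RdRp
#'   length distribution in aa (defaults 1036, 30, 986-1134).
#' @param normal_len_mean,normal_len_sd,normal_len_range Normal-class RdRp
#'   length distribution (defaults 761, 100, 556-1136).
#' @param theta_uga_large,theta_uga_normal Per-Trp UGA probability by class
#'   (defaults 0.014 and 0.30).
#' @param trp_density Expected Trp per 100 aa (default 1.3).
#' @param utr_len_mean,utr_len_sd UTR length distribution in nt
#'   (defaults 60, 15).
#' @param seed Integer seed; equal seeds give identical output.
#' @return List: `genomes` (named character vector of RNA genomes) and
#'   `truth` (data.frame: genome_id, class, rdrp_start, rdrp_end (0-based
#'   half-open, stop included), length_aa, theta_uga, motif_offset (0-based
#'   aa, NA for normal class), n_trp, n_uga).
#' @export
gen_genomes <- function(n_large = 8L, n_normal = 6L, motif,
                        large_len_mean = 1036, large_len_sd = 30,
                        large_len_range = c(986, 1134),
                        normal_len_mean = 761, normal_len_sd = 100,
                        normal_len_range = c(556, 1136),
                        theta_uga_large = 0.014, theta_uga_normal = 0.30,
                        trp_density = 1.3,
                        utr_len_mean = 60, utr_len_sd = 15, seed = 1L) {
  stopifnot(n_large >= 0L, n_normal >= 0L, n_large + n_normal >= 1L)
  stopifnot(theta_uga_large >= 0, theta_uga_large <= 1,
            theta_uga_normal >= 0, theta_uga_normal <= 1)
  width <- nchar(motif)
  if (grepl("W", motif, fixed = TRUE)) {
    stop("motif must not contain Trp (Trp codon usage is parameterized)")
  }
  if (width + 50 > large_len_range[1]) {
    stop("motif too long for the large-class RdRp length range")
  }
  .with_seed(seed, {
    classes <- c(rep("large", n_large), rep("normal", n_normal))
    n <- length(classes)
    ids <- sprintf("sim%03d", seq_len(n))
    lens <- integer(n)
    lens[classes == "large"] <- .trunc_norm_len(
      n_large, large_len_mean, large_len_sd, large_len_range)
    lens[classes == "normal"] <- .trunc_norm_len(
      n_normal, normal_len_mean, normal_len_sd, normal_len_range)
    genomes <- character(n)
    truth <- vector("list", n)
    motif_aa <- strsplit(motif, "", fixed = TRUE)[[1]]
    for (i in seq_len(n)) {
      len <- lens[i]
      aa <- .rand_protein(len, trp_density)
      moff <- NA_integer_
      if (classes[i] == "large") {
        moff <- sample.int(100L - width, 1L)  # 0-based start in 1..100-width
        aa[(moff + 1L):(moff + width)] <- motif_aa
      }
      theta <- if (classes[i] == "large") theta_uga_large else theta_uga_normal
      codons <- .codons_for(aa, theta)
      stop_codon <- sample(c("UAA", "UAG"), 1L)
      utr5 <- .rand_utr(max(0L, round(stats::rnorm(1, utr_len_mean, utr_len_sd))))
      utr3 <- .rand_utr(max(0L, round(stats::rnorm(1, utr_len_mean, utr_len_sd))))
      genomes[i] <- paste0(utr5, paste(codons, collapse = ""), stop_codon, utr3)
      truth[[i]] <- data.frame(
        genome_id = ids[i], class = classes[i],
        rdrp_start = nchar(utr5), rdrp_end = nchar(utr5) + 3L * (len + 1L),
        length_aa = len, theta_uga = theta, motif_offset = moff,
        n_trp = sum(codons %in% c("UGA", "UGG")),
        n_uga = sum(codons == "UGA"), stringsAsFactors = FALSE)
    }
    names(genomes) <- ids
    list(genomes = genomes, truth = do.call(rbind, truth))
  })
}

#' Generate a labelled reference protein set
#'
#' Random reference proteins with genus and host-taxon labels, optionally
#' with planted similarity families (a family seed plus mutated copies) so
#' top-hit assignment has recoverable structure.
#'
#' @param n_refs Number of independent references (default 105).
#' @param len_range Protein length range in aa (default 300-700).
#' @param genera,hosts Label vocabularies sampled uniformly.
#' @param n_families Number of planted families (default 0).
#' @param family_size Mutated copies per family seed (default 5).
#' @param family_identity Expected identity of copies to their seed
#'   (default 0.9).
#' @param seed Integer seed.
#' @return List: `refs` (named character vector), `labels` (data.frame
#'   ref_id, genus, host_taxon, family; family is NA outside planted
#'   families and names the seed ref for members).
#' @export
gen_reference_set <- function(n_refs = 105L, len_range = c(300, 700),
                              genera = c("Unuamitovirus", "Duamitovirus",
                                         "Triamitovirus", "Kvaramitovirus"),
                              hosts = c("Ascomycota", "Basidiomycota",
                                        "Glomeromycotina", "Zoopagomycota",
                                        "plant"),
                              n_families = 0L, family_size = 5L,
                              family_identity = 0.9, seed = 1L) {
  stopifnot(n_refs >= 2L)
  .with_seed(seed, {
    ids <- sprintf("ref%03d", seq_len(n_refs))
    lens <- sample(len_range[1]:len_range[2], n_refs, replace = TRUE)
    refs <- vapply(lens, function(l) {
      paste(.rand_protein(l, trp_density = 1.3), collapse = "")
    }, character(1))
    names(refs) <- ids
    labels <- data.frame(ref_id = ids,
                         genus = sample(genera, n_refs, replace = TRUE),
                         host_taxon = sample(hosts, n_refs, replace = TRUE),
                         family = NA_character_,
                         stringsAsFactors = FALSE)
    if (n_families > 0L) {
      stopifnot(n_families <= n_refs)
      for (f in seq_len(n_families)) {
        seed_id <- ids[f]
        seed_aa <- strsplit(refs[[seed_id]], "", fixed = TRUE)[[1]]
        for (m in seq_len(family_size)) {
          mid <- sprintf("%s_fam%02d", seed_id, m)
          refs[[mid]] <- paste(.mutate_protein(seed_aa, 1 - family_identity),
                               collapse = "")
          labels <- rbind(labels, data.frame(
            ref_id = mid, genus = labels$genus[f],
            host_taxon = labels$host_taxon[f], family = seed_id,
            stringsAsFactors = FALSE))
        }
      }
    }
    list(refs = refs, labels = labels)
  })
}

.default_groups <- function() {
  data.frame(
    genus = c("Duamitovirus", "Duamitovirus", "Duamitovirus",
              "Unuamitovirus", "Unuamitovirus", "Unuamitovirus",
              "Triamitovirus", "Kvaramitovirus", "large_dua-like"),
    host_taxon = c("Ascomycota", "Basidiomycota", "Glomeromycotina",
                   "Ascomycota", "plant", "Zoopagomycota",
                   "Basidiomycota", "Crustacea", "Glomeromycotina"),
    stringsAsFactors = FALSE)
}

# Poisson slope b giving Cor(X, Y) = rho when X ~ NB(mu, size) and
# Y | X ~ Poisson(a + b X): from Cov = b Var(X) and
# Var(Y) = a + b mu + b^2 Var(X).
.cooccur_slope <- function(rho, a, mu, v) {
  if (rho == 0) return(0)
  r2 <- rho^2
  (r2 * mu + sqrt(r2^2 * mu^2 + 4 * v * (1 - r2) * r2 * a)) /
    (2 * v * (1 - r2))
}

#' Simulate a mitovirus metatranscriptome community with ground truth
#'
#' Sites carry a latent standard-normal gradient driving group abundances
#' through a log link; the per-library ecosystem factor is tied to the same
#' gradient (soil probability rises with it) while sample type is pure
#' noise. Separately, per-library counts of other mitoviruses are drawn
#' negative-binomial and large-duamitovirus counts Poisson with a mean
#' linear in the other-mitovirus count, the slope set so the planted
#' correlation is `rho`.
#'
#' @param n_sites Number of study sites (default 20).
#' @param n_libraries Number of sequencing libraries (default 184).
#' @param rho Planted large-vs-other per-library correlation (default 0.6).
#' @param gradient_effect Log-scale coefficient linking the site gradient
#'   and group loadings to abundances (default 1; 0 plants no structure).
#' @param base_abundance Expected per-site per-group count at gradient 0
#'   (default 8).
#' @param nb_mu,nb_size Negative-binomial mean and dispersion of per-library
#'   other-mitovirus counts (defaults 30 and 5).
#' @param large_base Baseline large-duamitovirus mean count (default 2).
#' @param groups data.frame of genus / host_taxon group keys (default nine
#'   realistic combinations).
#' @param seed Integer seed.
#' @return List: `assignments` (query_id, genus, host_taxon),
#'   `meta` (per sequence: seq_id, library_id, site_id, ecosystem,
#'   sample_type), `library_meta` (per library), and `truth` (sites with
#'   gradients, group loadings, per-library planted counts, slope b).
#' @export
gen_community <- function(n_sites = 20L, n_libraries = 184L, rho = 0.6,
                          gradient_effect = 1, base_abundance = 8,
                          nb_mu = 30, nb_size = 5, large_base = 2,
                          groups = .default_groups(), seed = 1L) {
  stopifnot(n_libraries >= n_sites, n_sites >= 2L, abs(rho) < 1)
  .with_seed(seed, {
    site_ids <- sprintf("site%02d", seq_len(n_sites))
    gradient <- stats::rnorm(n_sites)
    lib_ids <- sprintf("lib%03d", seq_len(n_libraries))
    lib_site <- site_ids[rep_len(seq_len(n_sites), n_libraries)]
    lib_grad <- gradient[match(lib_site, site_ids)]
    ecosystem <- ifelse(stats::runif(n_libraries) <
                          stats::plogis(2 * lib_grad), "soil", "aquatic")
    sample_type <- sample(c("bulk_soil", "rhizosphere", "root"),
                          n_libraries, replace = TRUE)
    library_meta <- data.frame(library_id = lib_ids, site_id = lib_site,
                               ecosystem = ecosystem,
                               sample_type = sample_type,
                               stringsAsFactors = FALSE)
    n_groups <- nrow(groups)
    loading <- seq(-1, 1, length.out = n_groups)
    assignments <- list()
    meta <- list()
    q <- 0L
    for (s in seq_len(n_sites)) {
      libs_s <- lib_ids[lib_site == site_ids[s]]
      for (g in seq_len(n_groups)) {
        lambda <- base_abundance *
          exp(gradient_effect * gradient[s] * loading[g])
        cnt <- stats::rpois(1, lambda)
        if (cnt == 0L) next
        qid <- sprintf("q%06d", q + seq_len(cnt))
        q <- q + cnt
        lib <- sample(libs_s, cnt, replace = TRUE)
        assignments[[length(assignments) + 1L]] <- data.frame(
          query_id = qid, genus = groups$genus[g],
          host_taxon = groups$host_taxon[g], stringsAsFactors = FALSE)
        meta[[length(meta) + 1L]] <- data.frame(
          seq_id = qid, library_id = lib, site_id = site_ids[s],
          stringsAsFactors = FALSE)
      }
    }
    assignments <- do.call(rbind, assignments)
    meta <- do.call(rbind, meta)
    meta$ecosystem <- library_meta$ecosystem[match(meta$library_id, lib_ids)]
    meta$sample_type <-
      library_meta$sample_type[match(meta$library_id, lib_ids)]
    v <- nb_mu + nb_mu^2 / nb_size
    b <- .cooccur_slope(rho, large_base, nb_mu, v)
    n_other <- stats::rnbinom(n_libraries, mu = nb_mu, size = nb_size)
    n_large <- stats::rpois(n_libraries, large_base + b * n_other)
    truth <- list(
      sites = data.frame(site_id = site_ids, gradient = gradient,
                         stringsAsFactors = FALSE),
      groups = cbind(groups, loading = loading),
      library_counts = data.frame(library_id = lib_ids,
                                  n_large = n_large, n_other = n_other,
                                  stringsAsFactors = FALSE),
      slope_b = b, rho = rho)
    list(assignments = assignments, meta = meta,
         library_meta = library_meta, truth = truth)
  })
}
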