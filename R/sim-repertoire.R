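# Run code with a temporarily seeded RNG, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Repertoire simulation configuration
#'
#' Parameters of the synthetic B-cell repertoire generator. The defaults
#' emulate the structure of a caecal plasma-cell repertoire traced into
#' distal compartments: tens of clonal lineages expanded over ~1500 heavy
#' chains, power-law clone sizes, a caecal single-cell fraction with paired
#' light chains, bulk heavy-chain reads disseminated over blood, spleen,
#' lymph nodes and bone marrow, IgA-dominated isotypes (83% IgA, the
#' mucosal plasma-cell norm), and somatic hypermutation accumulated on V
#' genes.
#'
#' @param n_lineages number of clonal lineages (default 50).
#' @param n_sequences total heavy chains across all lineages (default 1500).
#' @param clone_size_exponent power-law exponent for expected clone sizes
#'   (weights proportional to rank^-exponent; default 1.0).
#' @param shm_rate_per_site per-site V-gene substitution probability per
#'   member (default 0.02, i.e. ~2% SHM).
#' @param cdr3_mutation_max_fraction upper bound on the fraction of CDR3
#'   positions substituted in any member relative to the lineage ancestor
#'   (default 0.10, half the clustering threshold so recovery is clean).
#' @param cdr3_mismatch_max_fraction the clustering threshold the analysis
#'   will use; ancestors of distinct lineages sharing a V/J/length key are
#'   rejected until they differ by more than
#'   `cdr3_mismatch_max_fraction + 2 * cdr3_mutation_max_fraction`, which
#'   guarantees no cross-lineage pair can fall inside the threshold.
#' @param fraction_single_cell probability a member is a caecal single cell
#'   with a paired light chain (default 0.25).
#' @param sc_tissue tissue label of single-cell members (default "caecum").
#' @param bulk_tissues compartments holding bulk heavy-chain libraries.
#' @param tissue_base_probs expected dissemination probabilities over
#'   `bulk_tissues` (the Dirichlet mean; default uniform).
#' @param tissue_concentration Dirichlet concentration for per-lineage
#'   dissemination draws; `Inf` (the default) pins every lineage to
#'   `tissue_base_probs` so pooled counts are exactly multinomial, finite
#'   values make dissemination patchier per lineage.
#' @param isotype_probabilities named probabilities per isotype, summing
#'   to 1.
#' @param n_v,n_j number of synthetic heavy germline V and J alleles.
#' @param v_length,j_length,c_length germline segment lengths (nt).
#' @param cdr3_lengths candidate CDR3 nucleotide lengths.
#' @param seed integer RNG seed; the generator is a pure function of this
#'   configuration.
#' @return A validated list of class `repertoire_config`.
#' @export
repertoire_config <- function(n_lineages = 50L,
                              n_sequences = 1500L,
                              clone_size_exponent = 1.0,
                              shm_rate_per_site = 0.02,
                              cdr3_mutation_max_fraction = 0.10,
                              cdr3_mismatch_max_fraction = 0.20,
                              fraction_single_cell = 0.25,
                              sc_tissue = "caecum",
                              bulk_tissues = c("PBMC", "spleen",
                                               "mesenteric_LN", "axillary_LN",
                                               "bone_marrow"),
                              tissue_base_probs = NULL,
                              tissue_concentration = Inf,
                              isotype_probabilities = c(
                                IgA = 0.83, IgM = 0.07, IgG1 = 0.04,
                                IgG2 = 0.03, IgG3 = 0.02, IgE = 0.01
                              ),
                              n_v = 25L, n_j = 6L,
                              v_length = 300L, j_length = 48L,
                              c_length = 100L,
                              cdr3_lengths = seq(24L, 60L, by = 3L),
                              seed = 1L) {
  if (is.null(tissue_base_probs)) {
    tissue_base_probs <- rep(1 / length(bulk_tissues), length(bulk_tissues))
  }
  cfg <- list(
    n_lineages = as.integer(n_lineages), n_sequences = as.integer(n_sequences),
    clone_size_exponent = clone_size_exponent,
    shm_rate_per_site = shm_rate_per_site,
    cdr3_mutation_max_fraction = cdr3_mutation_max_fraction,
    cdr3_mismatch_max_fraction = cdr3_mismatch_max_fraction,
    fraction_single_cell = fraction_single_cell,
    sc_tissue = sc_tissue, bulk_tissues = bulk_tissues,
    tissue_base_probs = tissue_base_probs,
    tissue_concentration = tissue_concentration,
    isotype_probabilities = isotype_probabilities,
    n_v = as.integer(n_v), n_j = as.integer(n_j),
    v_length = as.integer(v_length), j_length = as.integer(j_length),
    c_length = as.integer(c_length),
    cdr3_lengths = as.integer(cdr3_lengths),
    seed = as.integer(seed)
  )
  if (cfg$n_lineages < 1 || cfg$n_sequences < cfg$n_lineages) {
    abort("need n_sequences >= n_lineages >= 1")
  }
  if (abs(sum(cfg$isotype_probabilities) - 1) > 1e-9) {
    abort("isotype_probabilities must sum to 1")
  }
  if (abs(sum(cfg$tissue_base_probs) - 1) > 1e-9) {
    abort("tissue_base_probs must sum to 1")
  }
  if (length(cfg$tissue_base_probs) != length(cfg$bulk_tissues)) {
    abort("tissue_base_probs must match bulk_tissues in length")
  }
  if (cfg$shm_rate_per_site < 0 || cfg$shm_rate_per_site >= 1 ||
      cfg$cdr3_mutation_max_fraction < 0 || cfg$cdr3_mutation_max_fraction > 1) {
    abort("rates must be fractions")
  }
  structure(cfg, class = c("repertoire_config", "list"))
}

# sample() treats a length-1 numeric vector as 1:x; always index instead
sample_from <- function(x, n = 1, prob = NULL) {
  x[sample.int(length(x), n, replace = n > length(x), prob = prob)]
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly k positions, always to a different base
substitute_nt <- function(seq, k) {
  if (k == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# per-site substitution at rate r; returns c(sequence, n_mutations)
mutate_per_site <- function(seq, r) {
  if (r == 0) return(list(seq = seq, k = 0L))
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < r)
  for (p in hit) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  list(seq = paste(chars, collapse = ""), k = length(hit))
}

# synthetic germline reference set (named nucleotide vectors)
make_germline <- function(cfg) {
  vh <- setNames(
    vapply(seq_len(cfg$n_v), function(i) random_nt(cfg$v_length), character(1)),
    sprintf("IGHV%d-1*01", seq_len(cfg$n_v))
  )
  jh <- setNames(
    vapply(seq_len(cfg$n_j), function(i) random_nt(cfg$j_length), character(1)),
    sprintf("IGHJ%d*01", seq_len(cfg$n_j))
  )
  vk <- setNames(
    vapply(1:8, function(i) random_nt(cfg$v_length), character(1)),
    sprintf("IGKV%d-1*01", 1:8)
  )
  jk <- setNames(
    vapply(1:4, function(i) random_nt(cfg$j_length), character(1)),
    sprintf("IGKJ%d*01", 1:4)
  )
  vl <- setNames(
    vapply(1:8, function(i) random_nt(cfg$v_length), character(1)),
    sprintf("IGLV%d-1*01", 1:8)
  )
  jl <- setNames(
    vapply(1:4, function(i) random_nt(cfg$j_length), character(1)),
    sprintf("IGLJ%d*01", 1:4)
  )
  cc <- setNames(
    vapply(names(cfg$isotype_probabilities),
           function(i) random_nt(cfg$c_length), character(1)),
    names(cfg$isotype_probabilities)
  )
  list(heavy_v = vh, heavy_j = jh, kappa_v = vk, kappa_j = jk,
       lambda_v = vl, lambda_j = jl, constant = cc)
}

#' Simulate a clonal B-cell repertoire with ground truth
#'
#' Generates annotated heavy (and paired light) chain rearrangements from
#' `n_lineages` clonal families. Each lineage has one naive ancestor
#' (sampled V and J alleles plus a random CDR3); members carry independent
#' per-site somatic hypermutation on the V gene and at most
#' `cdr3_mutation_max_fraction` substitutions on the CDR3. Ancestors of
#' distinct lineages that share a (V, J, CDR3-length) key are re-drawn
#' until they are separated by more than the clustering threshold plus
#' twice the intra-clone bound, so the true partition is recoverable.
#' Single-cell members receive a paired light chain from the lineage's
#' light ancestor and the caecal tissue label; bulk members receive a
#' tissue drawn from the lineage's dissemination multinomial and a
#' duplicate count. Isotypes are sampled per member and the matching
#' constant-region reference sequence is attached. The output is a pure
#' function of the configuration (seed included).
#'
#' @param config a [repertoire_config()].
#' @param max_retries rejection budget per ancestor CDR3 before erroring.
#' @return A list with
#'   \describe{
#'     \item{records}{rearrangement tibble (heavy + light rows) accepted by
#'       [infer_lineages()] and [write_airr()].}
#'     \item{truth}{ground-truth labels: `sequences` (sequence_id,
#'       true_lineage_id), `lineage_tissue_probs` (per-lineage dissemination
#'       probabilities, long), `lineage_tissue_counts` (realized
#'       duplicate-weighted per-tissue reads per lineage), and the marginal
#'       `tissue_base_probs` / `isotype_probabilities` used.}
#'     \item{germline}{the synthetic germline reference set.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_repertoire(repertoire_config(n_lineages = 4,
#'                                              n_sequences = 40, seed = 2))
#' dplyr::count(sim$records, locus)
#' @export
simulate_repertoire <- function(config = repertoire_config(),
                                max_retries = 2000L) {
  cfg <- config
  with_seed(cfg$seed, {
    germ <- make_germline(cfg)

    # lineage ancestors, with rejection keeping same-key ancestors separable
    sep_min <- cfg$cdr3_mismatch_max_fraction + 2 * cfg$cdr3_mutation_max_fraction
    anc <- vector("list", cfg$n_lineages)
    for (l in seq_len(cfg$n_lineages)) {
      v <- sample(names(germ$heavy_v), 1)
      j <- sample(names(germ$heavy_j), 1)
      len <- sample_from(cfg$cdr3_lengths)
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cdr3 <- random_nt(len)
        clash <- FALSE
        for (a in anc[seq_len(l - 1)]) {
          if (is.null(a)) next
          if (a$v == v && a$j == j && nchar(a$cdr3) == len &&
              hamming_fraction(a$cdr3, cdr3) <= sep_min) {
            clash <- TRUE
            break
          }
        }
        if (!clash) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort("could not place distinct lineage ancestors; reduce n_lineages or widen cdr3_lengths")
      }
      light_locus <- sample(c("IGK", "IGL"), 1)
      lv <- if (light_locus == "IGK") germ$kappa_v else germ$lambda_v
      lj <- if (light_locus == "IGK") germ$kappa_j else germ$lambda_j
      anc[[l]] <- list(
        v = v, j = j, cdr3 = cdr3,
        v_seq = unname(germ$heavy_v[v]), j_seq = unname(germ$heavy_j[j]),
        light_locus = light_locus,
        light_v = sample(names(lv), 1), light_j = sample(names(lj), 1),
        light_cdr3 = random_nt(sample_from(cfg$cdr3_lengths)),
        tissue_probs = if (is.finite(cfg$tissue_concentration)) {
          g <- stats::rgamma(length(cfg$bulk_tissues),
                             shape = cfg$tissue_concentration * cfg$tissue_base_probs)
          g / sum(g)
        } else {
          cfg$tissue_base_probs
        }
      )
    }

    # power-law clone sizes: one guaranteed member each, rest multinomial
    w <- seq_len(cfg$n_lineages)^(-cfg$clone_size_exponent)
    extra <- cfg$n_sequences - cfg$n_lineages
    extra_alloc <- if (extra > 0) {
      as.integer(rmultinom(1, extra, w / sum(w)))
    } else {
      integer(cfg$n_lineages)
    }
    sizes <- 1L + extra_alloc

    rows <- vector("list", cfg$n_sequences * 2L)
    truth_rows <- vector("list", cfg$n_sequences)
    ri <- 0L
    si <- 0L
    cell_i <- 0L
    iso_names <- names(cfg$isotype_probabilities)
    for (l in seq_len(cfg$n_lineages)) {
      a <- anc[[l]]
      lineage_id <- sprintf("T%04d", l)
      for (m in seq_len(sizes[l])) {
        si <- si + 1L
        sid <- sprintf("S%06d", si)
        mut <- mutate_per_site(a$v_seq, cfg$shm_rate_per_site)
        max_k <- floor(cfg$cdr3_mutation_max_fraction * nchar(a$cdr3))
        k <- if (max_k > 0) sample(0:max_k, 1) else 0L
        cdr3 <- substitute_nt(a$cdr3, k)
        isotype <- sample_from(iso_names, prob = cfg$isotype_probabilities)
        is_sc <- runif(1) < cfg$fraction_single_cell
        if (is_sc) {
          cell_i <- cell_i + 1L
          cid <- sprintf("C%05d", cell_i)
          tis <- cfg$sc_tissue
          dup <- 1L
        } else {
          cid <- NA_character_
          tis <- sample_from(cfg$bulk_tissues, prob = a$tissue_probs)
          dup <- 1L + stats::rgeom(1, 0.6)
        }
        ri <- ri + 1L
        rows[[ri]] <- list(
          sequence_id = sid, locus = "IGH", v_call = a$v, j_call = a$j,
          cdr3 = cdr3, cell_id = cid, c_call = NA_character_,
          c_sequence = unname(germ$constant[isotype]), tissue = tis,
          source = if (is_sc) "single_cell" else "bulk",
          duplicate_count = dup,
          v_identity = 1 - mut$k / nchar(a$v_seq),
          v_sequence = mut$seq,
          sequence = paste0(mut$seq, cdr3, a$j_seq)
        )
        if (is_sc) {
          lmut <- mutate_per_site(
            if (a$light_locus == "IGK") germ$kappa_v[[a$light_v]] else germ$lambda_v[[a$light_v]],
            cfg$shm_rate_per_site
          )
          ri <- ri + 1L
          rows[[ri]] <- list(
            sequence_id = paste0(sid, "_L"), locus = a$light_locus,
            v_call = a$light_v, j_call = a$light_j, cdr3 = a$light_cdr3,
            cell_id = cid, c_call = NA_character_,
            c_sequence = NA_character_, tissue = tis,
            source = "single_cell", duplicate_count = 1L,
            v_identity = 1 - lmut$k / nchar(lmut$seq),
            v_sequence = lmut$seq, sequence = NA_character_
          )
        }
        truth_rows[[si]] <- list(
          sequence_id = sid, true_lineage_id = lineage_id,
          tissue = tis, source = if (is_sc) "single_cell" else "bulk",
          isotype = isotype, duplicate_count = dup
        )
      }
    }
    records <- as_rearrangement(bind_rows(rows[seq_len(ri)]))
    truth_seq <- bind_rows(truth_rows)

    lineage_tissue_probs <- bind_rows(lapply(seq_len(cfg$n_lineages), function(l) {
      tibble(true_lineage_id = sprintf("T%04d", l),
             tissue = cfg$bulk_tissues,
             prob = anc[[l]]$tissue_probs)
    }))
    lineage_tissue_counts <- truth_seq %>%
      filter(source == "bulk") %>%
      group_by(true_lineage_id, tissue) %>%
      summarise(n_members = n(), read_count = sum(duplicate_count),
                .groups = "drop")

    list(
      records = records,
      truth = list(
        sequences = truth_seq,
        lineage_tissue_probs = lineage_tissue_probs,
        lineage_tissue_counts = lineage_tissue_counts,
        tissue_base_probs = setNames(cfg$tissue_base_probs, cfg$bulk_tissues),
        isotype_probabilities = cfg$isotype_probabilities
      ),
      germline = germ,
      config = cfg
    )
  })
}
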