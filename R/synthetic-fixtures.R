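# Seeded synthetic inputs with planted ground truth. Sequences themselves are
# decorative random strings: every pairwise statistic the pipeline consumes
# (identities, coverages, TM/LDDT, hit names, labels, taxa, ipTM/pTM) is
# planted directly in the generated tables, because no stage of this package
# computes alignments. Within-family and between-family identity ranges must
# be separable so the planted partition is the unique solution at the default
# clustering thresholds.

#' Informative product vocabulary used by the fixture generator
#' @return Character vector of realistic phage protein product names.
#' @export
fixture_product_vocabulary <- function() {
  c("terminase large subunit", "major capsid protein", "portal protein",
    "minor tail protein", "tape measure protein", "tail assembly chaperone",
    "DNA polymerase III subunit epsilon", "integrase", "holin",
    "lysin A", "thymidylate synthase", "DNA primase", "endonuclease VII",
    "RecA-like recombinase", "glycosyltransferase", "ribonucleotide reductase")
}

#' Default synonym groups for the semantic-consistency check
#'
#' Equivalence classes of annotation strings that name the same function in
#' different vocabularies (structure-database names vs GenBank product
#' fields). Matching is case- and whitespace-insensitive.
#'
#' @return List of character vectors.
#' @export
default_synonym_groups <- function() {
  list(c("phage tail protein", "minor tail protein"),
       c("DNA polymerase III subunit epsilon", "DnaQ-like DNA polymerase III subunit"),
       c("terminase large subunit", "phage terminase, large subunit"),
       c("major capsid protein", "phage capsid protein"),
       c("lysin A", "endolysin"))
}

.void_hit_names <- c("putative protein", "hypothetical protein",
                     "uncharacterized protein", "domain of unknown function 4545")

# structure-database name for an informative hit: the synonym partner when
# the product belongs to a synonym group, else the product itself
.struct_name_for <- function(product, groups) {
  pn <- normalize_annotation(product)
  for (g in groups) {
    gn <- normalize_annotation(g)
    i <- match(pn, gn)
    if (!is.na(i)) return(g[if (i == 1L) min(2L, length(g)) else 1L])
  }
  product
}

#' Specification of a synthetic fixture
#'
#' Defines the study conditions the generator emulates: family structure and
#' identity separation for clustering, planted annotation fractions for the
#' rate formulas, a label-agreement probability for the consistency
#' statistics, model-confidence parameters, a taxonomy shape with a planted
#' superkingdom distribution for the LCA summaries, and interaction score
#' distributions for the network screens.
#'
#' @param seed Integer RNG seed.
#' @param n_families Number of protein families (planted clusters).
#' @param family_size Geometric family-size distribution:
#'   `list(prob=, max=)`; sizes are `1 + min(Geom(prob), max - 1)`.
#' @param within_identity_range Identity interval for within-family pairs;
#'   must lie entirely above both `between_identity_range` and the default
#'   clustering identity threshold.
#' @param between_identity_range Identity interval for between-family noise
#'   pairs.
#' @param frac_hypothetical Fraction of proteins whose GFF product is
#'   "hypothetical protein" (deterministic count `floor(frac * n)`).
#' @param frac_reps_with_hits Fraction of representatives receiving a
#'   structural best hit.
#' @param frac_void_hits Fraction of those hits with an uninformative (void)
#'   target name.
#' @param label_agreement_pi Probability that a family member carries its
#'   family's canonical Pfam/EC label rather than a member-unique decoy.
#' @param plddt_mean_sd Mean and SD of per-model mean pLDDT.
#' @param taxonomy_branching Children per node at the phylum, genus and
#'   species levels beneath each superkingdom.
#' @param superkingdom_probs Named probabilities for best-hit superkingdoms;
#'   an `unassigned` entry maps hits to the root.
#' @param n_phages Number of phages proteins are assigned to.
#' @param n_interactions,frac_true_pairs Interaction-table size and positive
#'   fraction.
#' @param pos_iptm,pos_ptm,neg_iptm,neg_ptm Uniform score ranges for
#'   positive and negative interaction pairs.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_families = 60L,
                         family_size = list(prob = 0.35, max = 20L),
                         within_identity_range = c(0.60, 0.95),
                         between_identity_range = c(0.05, 0.40),
                         frac_hypothetical = 0.66,
                         frac_reps_with_hits = 0.60,
                         frac_void_hits = 0.10,
                         label_agreement_pi = 0.90,
                         plddt_mean_sd = c(77, 10),
                         taxonomy_branching = c(3L, 3L, 3L),
                         superkingdom_probs = c(Bacteria = 0.6670,
                                                Eukaryota = 0.1527,
                                                Viruses = 0.0978,
                                                Archaea = 0.0427,
                                                unassigned = 0.0398),
                         n_phages = 24L,
                         n_interactions = 200L,
                         frac_true_pairs = 0.25,
                         pos_iptm = c(0.55, 0.95), pos_ptm = c(0.50, 0.95),
                         neg_iptm = c(0.02, 0.45), neg_ptm = c(0.02, 0.45)) {
  spec <- structure(as.list(environment()), class = "fixture_spec")
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  fracs <- c(spec$frac_hypothetical, spec$frac_reps_with_hits,
             spec$frac_void_hits, spec$label_agreement_pi, spec$frac_true_pairs)
  if (any(fracs < 0 | fracs > 1)) ph_stop("all fractions must lie in [0,1]")
  if (spec$within_identity_range[1] <= spec$between_identity_range[2]) {
    ph_stop(paste("non-separable identity ranges: within-family identities",
                  "must lie entirely above between-family identities"))
  }
  if (abs(sum(spec$superkingdom_probs) - 1) > 1e-6) {
    ph_stop("superkingdom_probs must sum to 1")
  }
  invisible(spec)
}

# deterministic planted count: floor, never rounds up
planted_count <- function(frac, n) as.integer(floor(frac * n + 1e-9))

with_fixture_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# largest-remainder apportionment of n items to probabilities p; the
# remainder goes to categories by decreasing fractional part (ties by order)
apportion <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(raw - base), seq_along(p))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  setNames(as.integer(base), names(p))
}

#' Generate a synthetic fixture bundle
#'
#' Draws a complete, internally consistent set of pipeline inputs with
#' planted ground truth: protein families with separable within/between
#' identities (so clustering at the default thresholds recovers the planted
#' partition exactly), products with a planted hypothetical fraction,
#' representative structure hits with planted void fraction, Pfam/EC labels
#' with a planted within-family agreement probability, pLDDT tracks, a
#' uniform taxonomy with a planted superkingdom distribution of best hits,
#' an interaction table mixing positive and negative score distributions,
#' and phage metadata. Regenerating with the same spec yields identical
#' results.
#'
#' @param spec A [fixture_spec()].
#' @return Object of class `fixture_bundle`; see the `truth` element for all
#'   planted values.
#' @export
generate_fixtures <- function(spec = fixture_spec()) {
  validate_fixture_spec(spec)
  with_fixture_rng(spec$seed, {
    nf <- spec$n_families
    sizes <- 1L + pmin(rgeom(nf, spec$family_size$prob),
                       spec$family_size$max - 1L)
    n <- sum(sizes)
    ids <- sprintf("MP%05d", seq_len(n))
    family_of <- rep(seq_len(nf), sizes)
    fam_members <- split(ids, family_of)
    reps <- vapply(fam_members, `[[`, "", 1L)  # lexicographically smallest
    planted <- new_clustering(setNames(fam_members, reps), provenance = "sequence")

    # phages & metadata
    phage_ids <- sprintf("phage_%03d", seq_len(spec$n_phages))
    metadata <- data.frame(
      phage_id = phage_ids,
      group = sample(LETTERS[1:6], spec$n_phages, replace = TRUE),
      lifestyle = rep(c("temperate", "lytic"), length.out = spec$n_phages),
      stringsAsFactors = FALSE)
    protein_to_phage <- setNames(sample(phage_ids, n, replace = TRUE), ids)

    # decorative sequences
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    seq_len_of <- sample(80:300, n, replace = TRUE)
    sequences <- data.frame(
      protein_id = ids,
      description = sprintf("synthetic protein, family %d", family_of),
      residues = vapply(seq_len_of,
                        function(L) paste(sample(aa, L, replace = TRUE), collapse = ""),
                        ""),
      stringsAsFactors = FALSE)

    # within-family pairwise alignments (complete graph per family)
    w <- spec$within_identity_range
    aln_rows <- list()
    for (f in seq_len(nf)) {
      m <- fam_members[[f]]
      if (length(m) < 2L) next
      pr <- utils::combn(m, 2L)
      k <- ncol(pr)
      aln_rows[[length(aln_rows) + 1L]] <- data.frame(
        query_id = pr[1L, ], target_id = pr[2L, ],
        seq_identity = runif(k, w[1], w[2]),
        query_cov = runif(k, 0.90, 1), target_cov = runif(k, 0.90, 1),
        evalue = 10^runif(k, -30, -5),
        tm_score = runif(k, 0.70, 0.99), lddt = runif(k, 0.70, 0.99),
        target_name = NA_character_, target_db = NA_character_,
        target_taxid = NA_integer_, stringsAsFactors = FALSE)
    }
    # sparse between-family noise rows (below the identity threshold)
    b <- spec$between_identity_range
    nb <- nf
    bi <- sample(n, nb, replace = TRUE)
    bj <- sample(n, nb, replace = TRUE)
    keep <- family_of[bi] != family_of[bj]
    if (any(keep)) {
      k <- sum(keep)
      aln_rows[[length(aln_rows) + 1L]] <- data.frame(
        query_id = ids[bi[keep]], target_id = ids[bj[keep]],
        seq_identity = runif(k, b[1], b[2]),
        query_cov = runif(k, 0.30, 1), target_cov = runif(k, 0.30, 1),
        evalue = 10^runif(k, -4, 1),
        tm_score = runif(k, 0.10, 0.45), lddt = runif(k, 0.10, 0.45),
        target_name = NA_character_, target_db = NA_character_,
        target_taxid = NA_integer_, stringsAsFactors = FALSE)
    }
    alignments <- do.call(rbind, aln_rows)
    rownames(alignments) <- NULL

    # products: planted hypothetical fraction, family-level informative names
    vocab <- fixture_product_vocabulary()
    fam_product <- vocab[(seq_len(nf) - 1L) %% length(vocab) + 1L]
    n_hyp <- planted_count(spec$frac_hypothetical, n)
    hyp_idx <- sample(n, n_hyp)
    product <- fam_product[family_of]
    product[hyp_idx] <- "hypothetical protein"
    products <- data.frame(protein_id = ids, product = product,
                           source = "sequence", stringsAsFactors = FALSE)

    # taxonomy: root -> 4 superkingdoms -> uniform phylum/genus/species
    tax <- build_uniform_taxonomy(spec$taxonomy_branching)

    # representative structure hits with planted void fraction
    n_hit <- planted_count(spec$frac_reps_with_hits, nf)
    hit_fams <- sort(sample(nf, n_hit))
    n_void <- planted_count(spec$frac_void_hits, n_hit)
    void_fams <- if (n_void > 0) sort(sample(hit_fams, n_void)) else integer()
    syn <- default_synonym_groups()
    sk_names <- names(spec$superkingdom_probs)
    sk_alloc <- apportion(spec$superkingdom_probs, n_hit)
    hit_sk <- sample(rep(sk_names, sk_alloc))
    hit_rows <- list()
    for (i in seq_along(hit_fams)) {
      f <- hit_fams[i]
      r <- reps[f]
      is_void <- f %in% void_fams
      nm <- if (is_void) {
        .void_hit_names[(f - 1L) %% length(.void_hit_names) + 1L]
      } else .struct_name_for(fam_product[f], syn)
      taxid <- taxid_for_superkingdom(tax, hit_sk[i])
      db <- sample(c("PDB", "AFDB_SwissProt", "AFDB"), 1L)
      best_tm <- runif(1, 0.55, 0.98)
      rows <- data.frame(
        query_id = r, target_id = sprintf("T%05d", f * 10L),
        seq_identity = runif(1, 0.15, 0.6),
        query_cov = runif(1, 0.82, 1), target_cov = runif(1, 0.82, 1),
        evalue = 10^runif(1, -20, -4), tm_score = best_tm,
        lddt = runif(1, 0.6, 0.98), target_name = nm, target_db = db,
        target_taxid = taxid, stringsAsFactors = FALSE)
      n_extra <- rbinom(1L, 2L, 0.5)
      if (n_extra > 0) {
        extra <- do.call(rbind, lapply(seq_len(n_extra), function(e) {
          data.frame(
            query_id = r, target_id = sprintf("T%05d", f * 10L + e),
            seq_identity = runif(1, 0.1, 0.5),
            query_cov = runif(1, 0.82, 1), target_cov = runif(1, 0.82, 1),
            evalue = 10^runif(1, -10, -2),
            tm_score = runif(1, 0.50, best_tm),
            lddt = runif(1, 0.5, 0.9), target_name = nm,
            target_db = sample(c("PDB", "AFDB_SwissProt", "AFDB"), 1L),
            target_taxid = taxid_for_superkingdom(tax, hit_sk[i]),
            stringsAsFactors = FALSE)
        }))
        rows <- rbind(rows, extra)
      }
      hit_rows[[i]] <- rows
    }
    struct_hits <- do.call(rbind, hit_rows) %||% empty_alignment_table()
    rownames(struct_hits) <- NULL

    # counter-defense library hits for a subset of representatives
    cd_names <- c("anti-CRISPR protein AcrIIA4", "antitoxin VapB15",
                  "antitoxin MazE", "anti-restriction protein ArdA")
    cd_fams <- sort(sample(nf, max(3L, nf %/% 10L)))
    cd_hits <- do.call(rbind, lapply(cd_fams, function(f) {
      data.frame(query_id = reps[f], target_id = sprintf("CD%03d", f),
                 seq_identity = runif(1, 0.1, 0.5),
                 query_cov = runif(1, 0.8, 1), target_cov = runif(1, 0.8, 1),
                 evalue = 10^runif(1, -8, -2), tm_score = runif(1, 0.45, 0.95),
                 lddt = runif(1, 0.5, 0.9),
                 target_name = sample(cd_names, 1L),
                 target_db = "counter_defense", target_taxid = NA_integer_,
                 stringsAsFactors = FALSE)
    }))

    # per-representative pLDDT tracks
    mu <- rnorm(nf, spec$plddt_mean_sd[1], spec$plddt_mean_sd[2])
    models <- lapply(seq_len(nf), function(f) {
      L <- min(seq_len_of[match(reps[f], ids)], 120L)
      v <- pmin(pmax(rnorm(L, mu[f], 4), 0), 100)
      structure(list(model_id = reps[f], plddt = v), class = "structure_model")
    })
    names(models) <- reps

    # Pfam / EC labels with planted within-family agreement probability
    pi <- spec$label_agreement_pi
    fam_pfam <- sprintf("PF%05d", 10000L + seq_len(nf))
    fam_ec <- sprintf("%d.%d.%d.%d", sample(1:6, nf, replace = TRUE),
                      sample(1:9, nf, replace = TRUE),
                      sample(1:9, nf, replace = TRUE),
                      sample(1:40, nf, replace = TRUE))
    agree_pfam <- runif(n) < pi
    agree_ec <- runif(n) < pi
    pfam_sets <- lapply(seq_len(n), function(i) {
      if (agree_pfam[i]) fam_pfam[family_of[i]] else sprintf("PF9%04d", i)
    })
    ec_first <- as.integer(substr(fam_ec[family_of], 1L, 1L))
    alt_first <- vapply(ec_first, function(x) sample(setdiff(1:7, x), 1L), 1L)
    ec_codes <- lapply(seq_len(n), function(i) {
      if (agree_ec[i]) fam_ec[family_of[i]]
      else sprintf("%d.%d.%d.%d", alt_first[i], sample(1:9, 1L),
                   sample(1:9, 1L), sample(1:40, 1L))
    })
    names(pfam_sets) <- ids
    names(ec_codes) <- ids

    # interaction table: positives high-scoring, negatives low-scoring
    n_int <- spec$n_interactions
    n_pos <- planted_count(spec$frac_true_pairs, n_int)
    host_pool <- sprintf("host_%02d", 1:12)
    is_pos <- c(rep(TRUE, n_pos), rep(FALSE, n_int - n_pos))
    interactions <- data.frame(
      phage_protein_id = sample(reps, n_int, replace = TRUE),
      host_protein_id = sample(host_pool, n_int, replace = TRUE),
      iptm = ifelse(is_pos, runif(n_int, spec$pos_iptm[1], spec$pos_iptm[2]),
                    runif(n_int, spec$neg_iptm[1], spec$neg_iptm[2])),
      ptm = ifelse(is_pos, runif(n_int, spec$pos_ptm[1], spec$pos_ptm[2]),
                   runif(n_int, spec$neg_ptm[1], spec$neg_ptm[2])),
      stringsAsFactors = FALSE)

    n_match <- sum(sizes[hit_fams])
    n_void_members <- sum(sizes[void_fams])
    truth <- list(
      n_proteins = n, n_families = nf, sizes = sizes,
      family_of = setNames(family_of, ids),
      n_hypothetical = n_hyp,
      expected_sequence_rate = (n - n_hyp) / n,
      hit_families = hit_fams, void_families = void_fams,
      n_match = n_match, n_void_members = n_void_members,
      expected_structure_rate = (n_match - n_void_members) / n,
      label_agreement_pi = pi,
      best_hit_superkingdoms = setNames(hit_sk, reps[hit_fams]),
      superkingdom_counts = sk_alloc,
      n_positive_interactions = n_pos)

    structure(list(spec = spec, sequences = sequences, alignments = alignments,
                   struct_hits = struct_hits, counter_defense_hits = cd_hits,
                   planted_clustering = planted, products = products,
                   pfam_labels = pfam_sets, ec_labels = ec_codes,
                   models = models, taxonomy = tax,
                   interactions = interactions, metadata = metadata,
                   protein_to_phage = protein_to_phage, truth = truth),
              class = "fixture_bundle")
  })
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d proteins in %d families (seed %d)\n",
              x$truth$n_proteins, x$truth$n_families, x$spec$seed))
  invisible(x)
}

# root(1) -> 4 superkingdoms -> branching[1] phyla -> branching[2] genera
# -> branching[3] species per genus
build_uniform_taxonomy <- function(branching = c(3L, 3L, 3L)) {
  sks <- c("Bacteria", "Archaea", "Eukaryota", "Viruses")
  taxid <- 1L; parent <- 1L; rank <- "no rank"; name <- "root"
  nxt <- 2L
  add <- function(p, r, nm) {
    taxid <<- c(taxid, nxt); parent <<- c(parent, p)
    rank <<- c(rank, r); name <<- c(name, nm)
    nxt <<- nxt + 1L
    nxt - 1L
  }
  for (sk in sks) {
    sk_id <- add(1L, "superkingdom", sk)
    for (p in seq_len(branching[1])) {
      p_id <- add(sk_id, "phylum", sprintf("%s phylum %d", sk, p))
      for (g in seq_len(branching[2])) {
        g_id <- add(p_id, "genus", sprintf("%s genus %d.%d", sk, p, g))
        for (s in seq_len(branching[3])) {
          add(g_id, "species", sprintf("%s species %d.%d.%d", sk, p, g, s))
        }
      }
    }
  }
  new_taxonomy_tree(taxid, parent, rank, name)
}

# random species-level taxid within a superkingdom ("unassigned" -> root)
taxid_for_superkingdom <- function(tree, sk) {
  if (sk == "unassigned") return(tree$root)
  sk_id <- tree$taxid[tree$rank == "superkingdom" & tree$name == sk]
  species <- tree$taxid[tree$rank == "species"]
  in_sk <- vapply(species, function(t) sk_id %in% root_path(tree, t), TRUE)
  sample(species[in_sk], 1L)
}

#' Analytic and Monte-Carlo expectations for a fixture spec
#'
#' Returns, for the study conditions encoded in a [fixture_spec()], the
#' values every downstream statistic should recover: the exact planted
#' sequence and structure annotation rates and superkingdom counts (exact
#' because the generator uses deterministic rounding), the analytic expected
#' label consistency (`pi^2`: an ordered pair agrees only when both members
#' carry the canonical family label, since decoy labels are member-unique),
#' a Monte-Carlo 99% interval for the mean cluster consistency averaged over
#' `n_seeds` independent fixtures, and the expected number of interactions
#' passing each screening threshold with its binomial standard deviation.
#'
#' @param spec A [fixture_spec()].
#' @param n_seeds Number of independent fixtures the consistency mean will be
#'   averaged over.
#' @param n_mc Monte-Carlo replicates for the interval.
#' @param thresholds Interaction screening thresholds.
#' @return List of expectations; see Details.
#' @export
expected_values <- function(spec = fixture_spec(), n_seeds = 1L, n_mc = 400L,
                            thresholds = c(0.5, 0.7)) {
  bundle <- generate_fixtures(spec)
  pi <- spec$label_agreement_pi

  mc <- with_fixture_rng(spec$seed + 777L, {
    one_mean <- function() {
      sizes <- 1L + pmin(rgeom(spec$n_families, spec$family_size$prob),
                         spec$family_size$max - 1L)
      sizes <- sizes[sizes >= 2L]
      if (length(sizes) == 0L) return(NA_real_)
      x <- rbinom(length(sizes), sizes, pi)
      mean(x * (x - 1) / (sizes * (sizes - 1)))
    }
    batch_means <- replicate(n_mc, mean(replicate(n_seeds, one_mean()), na.rm = TRUE))
    quantile(batch_means, c(0.005, 0.995), names = FALSE, na.rm = TRUE)
  })

  screen_exp <- lapply(thresholds, function(th) {
    ndraw <- 20000L
    draws <- with_fixture_rng(spec$seed + 999L, {
      pos <- interaction_score(runif(ndraw, spec$pos_iptm[1], spec$pos_iptm[2]),
                               runif(ndraw, spec$pos_ptm[1], spec$pos_ptm[2]))
      neg <- interaction_score(runif(ndraw, spec$neg_iptm[1], spec$neg_iptm[2]),
                               runif(ndraw, spec$neg_ptm[1], spec$neg_ptm[2]))
      c(p_pos = mean(pos > th), p_neg = mean(neg > th))
    })
    n_pos <- planted_count(spec$frac_true_pairs, spec$n_interactions)
    n_neg <- spec$n_interactions - n_pos
    expected <- n_pos * draws[["p_pos"]] + n_neg * draws[["p_neg"]]
    vr <- n_pos * draws[["p_pos"]] * (1 - draws[["p_pos"]]) +
      n_neg * draws[["p_neg"]] * (1 - draws[["p_neg"]])
    list(threshold = th, expected_count = expected, sd = sqrt(vr))
  })

  list(sequence_rate = bundle$truth$expected_sequence_rate,
       structure_rate = bundle$truth$expected_structure_rate,
       superkingdom_counts = bundle$truth$superkingdom_counts,
       consistency_mean = pi^2,
       consistency_interval_99 = mc,
       screened_interactions = screen_exp)
}

# ---------------------------------------------------------------------------
# Serialization of a bundle to the on-disk dialects consumed by formats_io

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "g"))
}

write_alignment_tsv <- function(aln, path, with_db = FALSE) {
  cols <- cbind(aln$query_id, aln$target_id,
                fmt_num(aln$seq_identity), fmt_num(aln$query_cov),
                fmt_num(aln$target_cov), fmt_num(aln$evalue),
                fmt_num(aln$tm_score), fmt_num(aln$lddt),
                ifelse(is.na(aln$target_name), "", aln$target_name),
                ifelse(is.na(aln$target_taxid), "", as.character(aln$target_taxid)))
  if (with_db) cols <- cbind(cols, ifelse(is.na(aln$target_db), "", aln$target_db))
  writeLines(apply(cols, 1L, paste, collapse = "\t"), path)
}

# column map matching write_alignment_tsv(with_db = TRUE)
fixture_hit_columns <- function() {
  c(query_id = 1L, target_id = 2L, seq_identity = 3L, query_cov = 4L,
    target_cov = 5L, evalue = 6L, tm_score = 7L, lddt = 8L,
    target_name = 9L, target_taxid = 10L, target_db = 11L)
}

write_minimal_pdb <- function(model, path) {
  n <- length(model$plddt)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), seq_len(n), seq_len(n) * 3.8, 0, 0, 1, model$plddt)
  writeLines(c(lines, "END"), path)
}

write_gff_products <- function(products, protein_to_phage, path) {
  phage <- protein_to_phage[products$protein_id]
  lines <- "##gff-version 3"
  for (p in sort(unique(phage))) {
    sub <- products[phage == p, , drop = FALSE]
    start <- seq_len(nrow(sub)) * 1000L - 999L
    attr_prod <- gsub("[;=&\t]", " ", sub$product)
    lines <- c(lines, sprintf(
      "%s\tphannot\tCDS\t%d\t%d\t.\t+\t0\tID=%s;product=%s",
      p, start, start + 500L, sub$protein_id, attr_prod))
  }
  writeLines(lines, path)
}

write_taxdump <- function(tree, dir) {
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|", tree$taxid, tree$parent, tree$rank)
  nms <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", tree$taxid, tree$name)
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  writeLines(nms, file.path(dir, "names.dmp"))
}

#' Write a fixture bundle to a directory of pipeline input files
#'
#' Emits every file dialect the pipeline consumes: `proteins.fasta`,
#' `cluster_alignments.tsv`, `struct_hits.tsv` (database hits including the
#' counter-defense library, 11 columns with a database tag),
#' `planted_clusters.tsv`, `products.gff`, `labels.tsv`, per-representative
#' PDB models under `models/`, `taxdump/nodes.dmp` + `names.dmp`,
#' `interactions.tsv`, `metadata.tsv`, `protein_to_phage.tsv` and the spec
#' as `spec.yaml`.
#'
#' @param bundle A [generate_fixtures()] bundle.
#' @param dir Output directory (created if needed).
#' @param write_models Write per-representative PDB files (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(bundle, dir, write_models = TRUE) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- sprintf(">%s %s\n%s", bundle$sequences$protein_id,
                bundle$sequences$description, bundle$sequences$residues)
  writeLines(fa, file.path(dir, "proteins.fasta"))
  write_alignment_tsv(bundle$alignments, file.path(dir, "cluster_alignments.tsv"))
  hits <- rbind(bundle$struct_hits, bundle$counter_defense_hits)
  write_alignment_tsv(hits, file.path(dir, "struct_hits.tsv"), with_db = TRUE)
  write_cluster_tsv(bundle$planted_clustering, file.path(dir, "planted_clusters.tsv"))
  write_gff_products(bundle$products, bundle$protein_to_phage,
                     file.path(dir, "products.gff"))
  labels <- data.frame(
    protein_id = names(bundle$pfam_labels),
    pfam = vapply(bundle$pfam_labels, paste, "", collapse = ","),
    ec = vapply(bundle$ec_labels, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (write_models) {
    mdir <- file.path(dir, "models")
    dir.create(mdir, showWarnings = FALSE)
    for (m in bundle$models) {
      write_minimal_pdb(m, file.path(mdir, paste0(m$model_id, ".pdb")))
    }
  }
  tdir <- file.path(dir, "taxdump")
  dir.create(tdir, showWarnings = FALSE)
  write_taxdump(bundle$taxonomy, tdir)
  write.table(bundle$interactions, file.path(dir, "interactions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(protein_id = names(bundle$protein_to_phage),
                         phage_id = unname(bundle$protein_to_phage),
                         stringsAsFactors = FALSE),
              file.path(dir, "protein_to_phage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  spec_plain <- lapply(unclass(bundle$spec), function(x) {
    if (is.numeric(x) || is.integer(x)) as.vector(x) else x
  })
  yaml::write_yaml(spec_plain, file.path(dir, "spec.yaml"))
  invisible(dir)
}
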