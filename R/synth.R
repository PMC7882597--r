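#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates the structure of curated GPCR-drug interaction
#' benchmarks: labelled pairs at roughly 1:2 class imbalance, sequences
#' whose encoded fragments form recoverable clusters, and pseudo-random
#' hexadecimal fingerprints with latent drug families.  Each GPCR is
#' assigned (round-robin) to one of `nMotifClusters` motif pools and each
#' drug to one of `nDrugFamilies` fingerprint families; a pair is
#' "compatible" when the cluster is bound to the family in the designated
#' compatibility map (cluster `i` binds family `(i - 1) %% nDrugFamilies
#' + 1`).  Labels are drawn as 1 with probability `beta` for compatible
#' pairs and `1 - beta` otherwise, then rejection-sampled to the target
#' positive fraction, so `beta = 0.5` gives label noise independent of
#' the features and `beta = 1` a deterministic rule.
#'
#' @param nGpcrs number of receptor sequences (default 60)
#' @param lengthRange sequence length range (default 100-300 residues)
#' @param nMotifClusters number of motif pools (default 3)
#' @param nDrugs number of drugs (default 40)
#' @param nDrugFamilies number of fingerprint families (default 2)
#' @param nPairs number of labelled pairs (default 390)
#' @param positiveFraction fraction of interactive pairs (default 1/3)
#' @param beta signal strength in \[0, 1\] (default 0.9)
#' @param mutationRate per-digit fingerprint noise within a family
#' @param seed integer seed (default 42)
#' @return configuration list
#' @export
synthConfig <- function(nGpcrs = 60L, lengthRange = c(100L, 300L),
                        nMotifClusters = 3L, nDrugs = 40L,
                        nDrugFamilies = 2L, nPairs = 390L,
                        positiveFraction = 1 / 3, beta = 0.9,
                        mutationRate = 0.15, seed = 42L) {
    stopifnot(nGpcrs > 0L, nDrugs > 0L, nPairs > 0L,
              positiveFraction > 0, positiveFraction < 1,
              beta >= 0, beta <= 1, nMotifClusters >= 1L,
              nDrugFamilies >= 1L)
    list(nGpcrs = as.integer(nGpcrs), lengthRange = as.integer(lengthRange),
         nMotifClusters = as.integer(nMotifClusters),
         nDrugs = as.integer(nDrugs), nDrugFamilies = as.integer(nDrugFamilies),
         nPairs = as.integer(nPairs), positiveFraction = positiveFraction,
         beta = beta, mutationRate = mutationRate, seed = as.integer(seed))
}

# latent assignments are a deterministic function of the config
gpcrClusters <- function(cfg)
    (seq_len(cfg$nGpcrs) - 1L) %% cfg$nMotifClusters + 1L
drugFamilies <- function(cfg)
    (seq_len(cfg$nDrugs) - 1L) %% cfg$nDrugFamilies + 1L
compatibleFamily <- function(cfg, cluster)
    (cluster - 1L) %% cfg$nDrugFamilies + 1L

#' Planted Gaussian fragment clusters
#'
#' A direct fixture for the silhouette statistic and K selection: `K`
#' unit-variance Gaussian blobs whose centers are pairwise at least
#' `separation` apart.
#'
#' @param K number of clusters (>= 2)
#' @param nPerCluster samples per cluster
#' @param dim dimensionality
#' @param separation minimum pairwise center distance
#' @param seed integer seed
#' @return list with `x` (matrix) and `labels` (integer vector)
#' @export
genFragmentClusters <- function(K, nPerCluster = 50L, dim = 2L,
                                separation = 10, seed = 1L) {
    stopifnot(K >= 2L)
    set.seed(seed)
    # centers are drawn in a compact box (side 3 x separation, grown only
    # if placement stalls) so pairwise separations stay comparable:
    # silhouette-style scores legitimately prefer merging a close pair of
    # clusters when the remaining clusters sit much farther away
    side <- 3 * separation
    centers <- matrix(stats::runif(dim, 0, side), 1L)
    tries <- 0L
    while (nrow(centers) < K) {
        cand <- stats::runif(dim, 0, side)
        d <- sqrt(rowSums((centers - matrix(cand, nrow(centers), dim,
                                            byrow = TRUE))^2))
        if (all(d >= separation)) {
            centers <- rbind(centers, cand)
            tries <- 0L
        } else if ((tries <- tries + 1L) > 200L) {
            side <- side + separation / 2
            tries <- 0L
        }
    }
    x <- do.call(rbind, lapply(seq_len(K), function(k)
        matrix(stats::rnorm(nPerCluster * dim), nPerCluster, dim) +
            matrix(centers[k, ], nPerCluster, dim, byrow = TRUE)))
    list(x = x, labels = rep(seq_len(K), each = nPerCluster))
}

# residue alphabets with distinct hydropathy profiles, one per motif pool
motifAlphabets <- function(n) {
    base <- list(c("I", "V", "L", "F"),     # strongly hydrophobic
                 c("R", "K", "D", "E"),     # strongly hydrophilic
                 c("G", "S", "T", "A"),     # near-neutral
                 c("C", "M", "W", "Y"),     # mixed mid-scale
                 c("P", "H", "N", "Q"))
    base[((seq_len(n) - 1L) %% length(base)) + 1L]
}

motifPools <- function(cfg, motifsPerPool = 6L, motifLength = 3L) {
    alph <- motifAlphabets(cfg$nMotifClusters)
    lapply(seq_len(cfg$nMotifClusters), function(k)
        vapply(seq_len(motifsPerPool), function(i)
            paste(sample(alph[[k]], motifLength, replace = TRUE),
                  collapse = ""), character(1)))
}

#' Generate synthetic receptor sequences
#'
#' Each sequence is a concatenation of tripeptide motifs drawn from its
#' cluster's motif pool, so hydropathy-encoded fragments form
#' recoverable clusters.  Only standard residues are emitted.
#'
#' @param cfg from [synthConfig()]
#' @return named character vector of sequences (`G1`, `G2`, ...)
#' @export
genSequences <- function(cfg = synthConfig()) {
    set.seed(cfg$seed + 101L)
    pools <- motifPools(cfg)
    cl <- gpcrClusters(cfg)
    lens <- sample(cfg$lengthRange[1L]:cfg$lengthRange[2L], cfg$nGpcrs,
                   replace = TRUE)
    seqs <- vapply(seq_len(cfg$nGpcrs), function(i) {
        pool <- pools[[cl[i]]]
        nMotif <- ceiling(lens[i] / nchar(pool[1L]))
        s <- paste(sample(pool, nMotif, replace = TRUE), collapse = "")
        substr(s, 1L, lens[i])
    }, character(1))
    names(seqs) <- paste0("G", seq_len(cfg$nGpcrs))
    seqs
}

#' Generate synthetic drug fingerprints
#'
#' Each family has a 256-hex-digit template; members copy the template
#' and mutate each digit independently with probability `mutationRate`,
#' so wavelet features are informative about the family.
#'
#' @param cfg from [synthConfig()]
#' @return named character vector of 256-character hex strings
#'   (`D1`, `D2`, ...)
#' @export
genFingerprints <- function(cfg = synthConfig()) {
    set.seed(cfg$seed + 202L)
    digits <- c(0:9, letters[1:6])
    templates <- replicate(cfg$nDrugFamilies,
                           sample(digits, 256L, replace = TRUE),
                           simplify = FALSE)
    fam <- drugFamilies(cfg)
    fps <- vapply(seq_len(cfg$nDrugs), function(i) {
        d <- templates[[fam[i]]]
        mut <- stats::runif(256L) < cfg$mutationRate
        d[mut] <- sample(digits, sum(mut), replace = TRUE)
        paste(d, collapse = "")
    }, character(1))
    names(fps) <- paste0("D", seq_len(cfg$nDrugs))
    fps
}

#' Generate labelled GPCR-drug pairs
#'
#' Walks a seeded random permutation of all (GPCR, drug) combinations,
#' draws each label from the compatibility rule (1 with probability
#' `beta` if compatible, `1 - beta` otherwise) and keeps pairs until the
#' positive and negative quotas implied by `nPairs` and
#' `positiveFraction` are filled.
#'
#' @param cfg from [synthConfig()]
#' @return data.frame with `gpcr_id`, `drug_id`, `label`
#' @export
genPairs <- function(cfg = synthConfig()) {
    set.seed(cfg$seed + 303L)
    needPos <- round(cfg$nPairs * cfg$positiveFraction)
    needNeg <- cfg$nPairs - needPos
    cl <- gpcrClusters(cfg)
    fam <- drugFamilies(cfg)
    combos <- expand.grid(g = seq_len(cfg$nGpcrs), d = seq_len(cfg$nDrugs))
    combos <- combos[sample.int(nrow(combos)), ]
    compat <- fam[combos$d] == compatibleFamily(cfg, cl[combos$g])
    p1 <- ifelse(compat, cfg$beta, 1 - cfg$beta)
    lab <- as.integer(stats::runif(nrow(combos)) < p1)
    keep <- logical(nrow(combos))
    nPos <- nNeg <- 0L
    for (i in seq_len(nrow(combos))) {
        if (lab[i] == 1L && nPos < needPos) { keep[i] <- TRUE; nPos <- nPos + 1L }
        else if (lab[i] == 0L && nNeg < needNeg) { keep[i] <- TRUE; nNeg <- nNeg + 1L }
        if (nPos == needPos && nNeg == needNeg) break
    }
    if (nPos < needPos || nNeg < needNeg)
        stop("could not fill the label quotas; increase nGpcrs/nDrugs ",
             "or lower nPairs")
    data.frame(gpcr_id = paste0("G", combos$g[keep]),
               drug_id = paste0("D", combos$d[keep]),
               label = lab[keep])
}

#' Generate the full synthetic benchmark
#'
#' Produces sequences, fingerprints and labelled pairs from one
#' configuration and optionally writes them in the pipeline's input
#' formats (FASTA, fingerprint TSV, pair TSV) plus a `truth.json` with
#' the latent cluster/family assignments.
#'
#' @param cfg from [synthConfig()]
#' @param dir optional output directory; created if missing
#' @return list with `sequences`, `fingerprints`, `pairs`, `truth`, and
#'   (when `dir` is given) `paths`
#' @export
generateBenchmark <- function(cfg = synthConfig(), dir = NULL) {
    seqs <- genSequences(cfg)
    fps <- genFingerprints(cfg)
    pairs <- genPairs(cfg)
    truth <- list(gpcrCluster = stats::setNames(as.list(gpcrClusters(cfg)),
                                                names(seqs)),
                  drugFamily = stats::setNames(as.list(drugFamilies(cfg)),
                                               names(fps)),
                  beta = cfg$beta, seed = cfg$seed)
    out <- list(sequences = seqs, fingerprints = fps, pairs = pairs,
                truth = truth)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        paths <- list(fasta = file.path(dir, "gpcrs.fasta"),
                      fingerprints = file.path(dir, "fingerprints.tsv"),
                      pairs = file.path(dir, "pairs.tsv"),
                      truth = file.path(dir, "truth.json"))
        writeLines(paste0(">", names(seqs), "\n", seqs), paths$fasta)
        utils::write.table(
            data.frame(id = names(fps), hex = unname(fps)),
            paths$fingerprints, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
        utils::write.table(pairs, paths$pairs, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE)
        out$paths <- paths
    }
    out
}
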