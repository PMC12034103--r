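#' Noise specification for the synthetic loop generator
#'
#' @param coord_sd standard deviation (Angstrom) of the isotropic Gaussian
#'   jitter added to each nucleotide center (default 0.3).
#' @param pair_drop_prob probability that a template base pair is dropped
#'   (default 0.05), emulating an annotation miss.
#' @param pair_flip_prob probability that a surviving base pair's LW class
#'   is replaced by a different random class (default 0.05), emulating an
#'   annotation conflict.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(coord_sd = 0.3, pair_drop_prob = 0.05,
                       pair_flip_prob = 0.05) {
  stopifnot(coord_sd >= 0, pair_drop_prob >= 0, pair_drop_prob <= 1,
            pair_flip_prob >= 0, pair_flip_prob <= 1)
  structure(list(coord_sd = coord_sd, pair_drop_prob = pair_drop_prob,
                 pair_flip_prob = pair_flip_prob), class = "noise_spec")
}

family_template <- function(name, seqs, bp, stk, rise, twist, radius,
                            kink_at = 0L, kink_angle = 0, strand_sep = 9) {
  lens <- nchar(seqs)
  n <- sum(lens)
  stopifnot(all(bp$i >= 1 & bp$i <= n), all(bp$j >= 1 & bp$j <= n),
            all(stk$i >= 1 & stk$i <= n), all(stk$j >= 1 & stk$j <= n))
  structure(list(name = name, seqs = seqs, strand_lens = lens,
                 base_pairs = bp, stackings = stk,
                 rise = rise, twist = twist, radius = radius,
                 kink_at = as.integer(kink_at), kink_angle = kink_angle,
                 strand_sep = strand_sep),
            class = "family_template")
}

bp_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), lw = m[, 3],
             stringsAsFactors = FALSE)
}
stk_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), direction = m[, 3],
             stringsAsFactors = FALSE)
}

#' Built-in synthetic motif family templates
#'
#' Six internal-loop and two hairpin-loop templates named after the known
#' motif families whose role they stand in for (Sarcin-ricin, Kink-turn,
#' Tandem-shear, Hook-turn, E-loop, C-loop; T-loop, GNRA tetraloop). The
#' geometries are parametric helices with optional kinks — synthetic
#' stand-ins exercising the pipeline, not real family structures. Any two
#' templates differ in at least two base-interaction pattern entries and at
#' least one geometric parameter.
#'
#' @return named list of 8 `family_template` objects.
#' @export
builtin_templates <- function() {
  list(
    SR = family_template("SR", c("CUCAG", "GAGG"),
      bp_df(1, 9, "cWW", 5, 6, "cWW", 2, 8, "tHS", 3, 7, "tSH", 4, 6, "tWH"),
      stk_df(1, 2, "upward", 2, 3, "upward", 6, 7, "upward", 3, 4, "inward"),
      rise = 3.0, twist = 0.90, radius = 4.0),
    KT = family_template("KT", c("GAAGAC", "GAUC"),
      bp_df(1, 10, "cWW", 6, 7, "cWW", 2, 9, "tHS", 3, 8, "tSH", 4, 8, "tSS"),
      stk_df(2, 3, "upward", 3, 4, "downward", 7, 8, "upward"),
      rise = 2.6, twist = 0.70, radius = 3.2, kink_at = 3, kink_angle = 1.2),
    TS = family_template("TS", c("GAGC", "GAGC"),
      bp_df(1, 8, "cWW", 4, 5, "cWW", 2, 7, "tSH", 3, 6, "tHS"),
      stk_df(1, 2, "upward", 5, 6, "upward"),
      rise = 3.4, twist = 1.10, radius = 3.8),
    HT = family_template("HT", c("UAAGC", "GCUUA"),
      bp_df(1, 10, "cWW", 5, 6, "cWW", 2, 9, "tWS", 3, 8, "cHH", 4, 7, "tWW"),
      stk_df(2, 3, "inward", 7, 8, "outward"),
      rise = 2.9, twist = 0.42, radius = 4.6, kink_at = 4, kink_angle = 1.0),
    EL = family_template("EL", c("AGUAU", "AUGA"),
      bp_df(1, 9, "cWW", 5, 6, "cWW", 2, 8, "tSH", 3, 7, "tHW", 4, 6, "cSW"),
      stk_df(1, 2, "upward", 6, 7, "downward"),
      rise = 4.4, twist = 0.45, radius = 5.6),
    CL = family_template("CL", c("CACGUA", "GGCAG"),
      bp_df(1, 11, "cWW", 6, 7, "cWW", 2, 10, "cSW", 4, 9, "tWH", 5, 8, "cHS"),
      stk_df(3, 4, "upward", 8, 9, "inward"),
      rise = 2.4, twist = 1.15, radius = 4.3, kink_at = 5, kink_angle = 0.5),
    TL = family_template("TL", c("CUGGAAG"),
      bp_df(1, 7, "cWW", 2, 6, "tWH"),
      stk_df(3, 4, "upward", 4, 5, "upward"),
      rise = 2.6, twist = 0.95, radius = 3.5, kink_at = 4, kink_angle = 1.4),
    GL = family_template("GL", c("CGAAAG"),
      bp_df(1, 6, "cWW", 2, 5, "tSH"),
      stk_df(2, 3, "upward", 3, 4, "upward"),
      rise = 1.9, twist = 1.85, radius = 2.0)
  )
}

#' Noise-free backbone centers of a template
#'
#' Strand 1 runs up a helix of the template's rise/twist/radius, bent by
#' `kink_angle` about the y axis after position `kink_at`; strand 2 (if any)
#' runs antiparallel, offset by `strand_sep` along x.
#'
#' @param template a `family_template`.
#' @return n x 3 matrix of nucleotide centers.
#' @export
template_centers <- function(template) {
  helix <- function(L, phase = 0) {
    t <- seq_len(L) - 1L
    cbind(template$radius * cos(template$twist * t + phase),
          template$radius * sin(template$twist * t + phase),
          template$rise * t)
  }
  p1 <- helix(template$strand_lens[1])
  if (template$kink_at > 0L && template$kink_at < nrow(p1)) {
    k <- template$kink_at
    a <- template$kink_angle
    R <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
    pivot <- p1[k, ]
    after <- (k + 1L):nrow(p1)
    p1[after, ] <- sweep(sweep(p1[after, , drop = FALSE], 2, pivot) %*% t(R),
                         2, pivot, `+`)
  }
  if (length(template$strand_lens) == 1L) return(p1)
  L2 <- template$strand_lens[2]
  t2 <- seq_len(L2) - 1L
  p2 <- cbind(template$strand_sep + template$radius * cos(template$twist * t2 + pi),
              template$radius * sin(template$twist * t2 + pi),
              template$rise * (template$strand_lens[1] - 1L) - template$rise * t2)
  rbind(p1, p2)
}

# fixed backbone-atom offsets from the nucleotide center (sum to zero so the
# atom mean recovers the center)
ATOM_OFFSETS <- matrix(c(
   1.2,  0.4, -0.6,   # P
   0.6, -0.8,  0.4,   # O5'
   0.1,  0.7,  0.5,   # C5'
  -0.4, -0.5, -0.7,   # C4'
  -0.7,  0.6, -0.1,   # C3'
  -0.8, -0.4,  0.5),  # O3'
  ncol = 3, byrow = TRUE,
  dimnames = list(c("P", "O5'", "C5'", "C4'", "C3'", "O3'"), NULL))

#' Minimum Kabsch RMSD between template center sets
#'
#' Pairwise over templates, truncating both center lists to the common
#' length. Used to verify the separability floor of the built-in set.
#'
#' @param templates list of `family_template`s.
#' @return minimum over all template pairs (Angstrom).
#' @export
min_template_rmsd <- function(templates = builtin_templates()) {
  cs <- lapply(templates, template_centers)
  best <- Inf
  for (a in seq_len(length(cs) - 1L)) for (b in (a + 1L):length(cs)) {
    k <- min(nrow(cs[[a]]), nrow(cs[[b]]))
    best <- min(best, kabsch_rmsd(cs[[a]][seq_len(k), ], cs[[b]][seq_len(k), ]))
  }
  best
}

#' Sample one noisy loop from a family template
#'
#' Deterministic given (template, noise, instance_seed): nucleotide centers
#' are the template backbone plus isotropic Gaussian jitter, the six
#' backbone atoms sit at fixed offsets from each center, and the annotation
#' pattern is the template pattern after drop/flip noise.
#'
#' @param template a `family_template`.
#' @param noise a [noise_spec()].
#' @param instance_seed integer seed for this instance.
#' @param instance_id integer used to build a unique synthetic location
#'   string (structure id `S` + base-36 counter).
#' @return an `rna_loop` with coordinates, annotations and family label.
#' @export
sample_loop <- function(template, noise = noise_spec(), instance_seed = 0L,
                        instance_id = 1L) {
  set.seed(instance_seed)
  centers <- template_centers(template)
  n <- nrow(centers)
  centers <- centers + matrix(stats::rnorm(3 * n, sd = noise$coord_sd), n, 3)

  bp <- template$base_pairs
  if (nrow(bp) > 0L) {
    keep <- stats::runif(nrow(bp)) >= noise$pair_drop_prob
    bp <- bp[keep, , drop = FALSE]
    if (nrow(bp) > 0L) {
      flip <- stats::runif(nrow(bp)) < noise$pair_flip_prob
      for (r in which(flip))
        bp$lw[r] <- sample(setdiff(LW_CLASSES, bp$lw[r]), 1L)
    }
  }
  digits36 <- c(0:9, LETTERS)
  code <- paste0(digits36[(instance_id %/% 36^2) %% 36 + 1],
                 digits36[(instance_id %/% 36) %% 36 + 1],
                 digits36[instance_id %% 36 + 1])
  lens <- template$strand_lens
  segs <- if (length(lens) == 1L) sprintf("1-%d", lens[1]) else
    sprintf("1-%d_101-%d", lens[1], 100L + lens[2])
  loc <- sprintf("S%s_A:%s", code, segs)
  bases <- unlist(strsplit(template$seqs, ""))
  nts <- lapply(seq_len(n), function(t) {
    xyz <- sweep(ATOM_OFFSETS, 2, centers[t, ], `+`)
    resno <- if (t <= lens[1]) t else 100L + (t - lens[1])
    nucleotide(resno, bases[t], coords = xyz)
  })
  rna_loop(loc, nts, bp, template$stackings, family = template$name)
}

#' Generate a labelled synthetic loop dataset with a stratified split
#'
#' `n_per_family` noisy instances of each template, with a per-family
#' stratified train/validation/test split (default 86% / 7% / 7%, the
#' proportions of the 253/20/20-style splits used for motif family
#' training sets). Fully deterministic given `seed`.
#'
#' @param templates list of `family_template`s (default all built-ins).
#' @param n_per_family instances per family.
#' @param noise a [noise_spec()].
#' @param seed master seed; per-instance seeds are derived from it.
#' @param split_frac numeric length-3 (train, val, test), summing to 1.
#' @return list with `loops`, `labels` (named by loop id), `split`
#'   (index vectors `train`, `val`, `test`) and a `manifest` data frame.
#' @export
generate_dataset <- function(templates = builtin_templates(), n_per_family = 50L,
                             noise = noise_spec(), seed = 0L,
                             split_frac = c(0.86, 0.07, 0.07)) {
  stopifnot(abs(sum(split_frac) - 1) < 1e-9)
  loops <- list(); fam <- character(0)
  inst <- 0L
  for (tmpl in templates) {
    for (r in seq_len(n_per_family)) {
      inst <- inst + 1L
      iseed <- (as.integer(seed) * 1000003L + inst * 7919L) %% 2147483647L
      loops[[inst]] <- sample_loop(tmpl, noise, iseed, inst)
      fam[inst] <- tmpl$name
    }
  }
  ids <- vapply(loops, loop_id, character(1))
  labels <- stats::setNames(fam, ids)
  set.seed(seed)
  split <- list(train = integer(0), val = integer(0), test = integer(0))
  for (f in unique(fam)) {
    idx <- sample(which(fam == f))
    n <- length(idx)
    n_val <- max(1L, round(n * split_frac[2]))
    n_test <- max(1L, round(n * split_frac[3]))
    split$val <- c(split$val, idx[seq_len(n_val)])
    split$test <- c(split$test, idx[n_val + seq_len(n_test)])
    split$train <- c(split$train, idx[(n_val + n_test + 1L):n])
  }
  part <- rep("train", length(loops))
  part[split$val] <- "val"; part[split$test] <- "test"
  list(loops = loops, labels = labels, split = split,
       manifest = data.frame(loop_id = ids, family = fam, split = part,
                             stringsAsFactors = FALSE))
}

#' Export loop annotations in an adapter dialect
#'
#' Rewrites a loop's base-pair and stacking annotations as the raw TSV rows
#' of the FR3D-style or DSSR-style adapter dialect (see
#' [normalize_records()]), so the annotation-merging workflow can be
#' exercised end to end on synthetic data.
#'
#' @param loop an `rna_loop`.
#' @param source `"FR3D"` or `"DSSR"`.
#' @return data frame in the adapter-dialect layout.
#' @export
adapter_rows_from_loop <- function(loop, source = c("FR3D", "DSSR")) {
  source <- match.arg(source)
  seg <- loop$location$segments
  lens <- seg$end - seg$start + 1L
  ends <- cumsum(lens)
  res_of <- function(t) {
    s <- which(t <= ends)[1]
    offset <- t - (ends[s] - lens[s])
    seg$start[s] + offset - 1L
  }
  mk <- function(i, j, kind, canon) {
    cls <- canon
    if (source == "DSSR") {
      if (kind == "pair")
        cls <- paste0(substr(canon, 1, 1), substr(canon, 2, 2), "-",
                      substr(canon, 3, 3))
    } else {
      if (kind == "stack")
        cls <- c(upward = "s35", downward = "s53", inward = "s33",
                 outward = "s55")[canon]
    }
    data.frame(structure_id = loop$location$pdb_id,
               chain_i = loop$location$chain, res_i = res_of(i),
               base_i = loop$nucleotides[[i]]$base,
               chain_j = loop$location$chain, res_j = res_of(j),
               base_j = loop$nucleotides[[j]]$base,
               kind = kind, class = unname(cls), stringsAsFactors = FALSE)
  }
  rows <- list()
  bp <- loop$base_pairs
  for (r in seq_len(nrow(bp)))
    rows[[length(rows) + 1L]] <- mk(bp$i[r], bp$j[r], "pair", bp$lw[r])
  stk <- loop$stackings
  for (r in seq_len(nrow(stk)))
    rows[[length(rows) + 1L]] <- mk(stk$i[r], stk$j[r], "stack", stk$direction[r])
  if (length(rows) == 0L)
    return(data.frame(structure_id = character(), chain_i = character(),
                      res_i = integer(), base_i = character(),
                      chain_j = character(), res_j = integer(),
                      base_j = character(), kind = character(),
                      class = character()))
  do.call(rbind, rows)
}
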