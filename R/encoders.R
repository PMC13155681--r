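# The three embedding subnetworks feeding the global synergy predictor:
#   Ed - character-level 1D-CNN over the SMILES string (shared by both drugs)
#   Er - fixed sinusoidal embedding of the (transformed) dose (shared)
#   Ec - three-layer ReLU MLP over the cell line's expression profile

## ---- SMILES vocabulary & tokenization --------------------------------------

#' Build a character vocabulary from a SMILES library
#'
#' Character-level vocabulary for the drug encoder. Index 0 is reserved for
#' padding (PAD) and index 1 for unknown characters (UNK); the observed
#' characters follow in sorted order, so indices are contiguous from 0.
#'
#' @param smiles Character vector of SMILES strings (typically the training
#'   drug library).
#' @param max_length Sequences are right-padded / truncated to this length.
#' @return An object of class `smiles_vocabulary`: list with `symbols`
#'   (character vector, position i = index i + 1), `index` (named integer
#'   map), `pad`, `unk`, `size`, `max_length`.
#' @export
smiles_vocabulary <- function(smiles, max_length = 128L) {
  stopifnot(length(smiles) > 0L, max_length >= 1L)
  chars <- sort(unique(unlist(strsplit(smiles, "", fixed = TRUE))))
  idx <- seq_along(chars) + 1L  # 0 = PAD, 1 = UNK
  structure(
    list(symbols = chars,
         index = stats::setNames(idx, chars),
         pad = 0L, unk = 1L,
         size = length(chars) + 2L,
         max_length = as.integer(max_length)),
    class = "smiles_vocabulary"
  )
}

#' Tokenize a SMILES string
#'
#' Character-by-character lookup against a [smiles_vocabulary()]: unknown
#' characters map to UNK, the sequence is right-padded with PAD and truncated
#' at `vocab$max_length`.
#'
#' @param smiles A single non-empty SMILES string.
#' @param vocab A `smiles_vocabulary`.
#' @return Integer vector of length `vocab$max_length`.
#' @export
tokenize_smiles <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  if (length(smiles) != 1L || is.na(smiles) || !nzchar(smiles)) {
    stop("smiles must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  ids <- unname(vocab$index[chars])
  ids[is.na(ids)] <- vocab$unk
  n <- vocab$max_length
  if (length(ids) >= n) ids[seq_len(n)] else c(ids, rep(vocab$pad, n - length(ids)))
}

# tokenize a library into an n_drugs x max_length integer matrix
tokenize_library <- function(smiles, vocab) {
  t(vapply(smiles, tokenize_smiles, integer(vocab$max_length), vocab = vocab))
}

## ---- sinusoidal dose embedding ---------------------------------------------

#' Configure the sinusoidal dose embedder
#'
#' The dose embedding maps a scalar dose d to
#' \deqn{[\sin(2\pi f_1 d), \cos(2\pi f_1 d), \ldots, \sin(2\pi f_c d), \cos(2\pi f_c d)]}
#' with frequencies f1 < ... < fc log-spaced between `f_min` and `f_max`.
#' The embedding is fixed (not learned). Before embedding, the raw assay dose
#' is passed through `transform`:
#' * `"log-min-max"` (default): d' = (log r - log r_min) / (log r_max - log r_min),
#'   using the training-set dose range, so d' lies in \[0, 1\] on the training
#'   grid. Raw micromolar doses span orders of magnitude and would alias the
#'   faster frequencies; log-min-max puts one slow period across the grid.
#' * `"identity"`: the raw dose is embedded as-is.
#'
#' Defaults c = 16, f_min = 0.1, f_max = 50 make the slowest wave span the
#' \[0, 1\] normalized range and the fastest resolve ~1% dose differences.
#' Setting `sinusoidal = FALSE` bypasses the trigonometric map and emits the
#' transformed dose itself as a 1-dimensional feature (the
#' "raw normalized dose" ablation).
#'
#' @param n_freq Number of frequencies c; output dimension is 2c.
#' @param f_min,f_max Positive frequency range, `f_min < f_max`.
#' @param transform `"log-min-max"` or `"identity"`.
#' @param dose_range Length-2 positive numeric, the (min, max) training dose
#'   used by `"log-min-max"`; usually filled in by the trainer via
#'   [set_dose_range()].
#' @param sinusoidal Logical; `FALSE` selects the raw-dose ablation variant.
#' @return An object of class `dose_embedder_config` with the derived
#'   `frequencies` and `dim` fields.
#' @export
dose_embedder_config <- function(n_freq = 16L, f_min = 0.1, f_max = 50,
                                 transform = c("log-min-max", "identity"),
                                 dose_range = NULL, sinusoidal = TRUE) {
  transform <- match.arg(transform)
  stopifnot(n_freq >= 1L, f_min > 0, f_max > f_min)
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n_freq))
  if (!is.null(dose_range)) {
    stopifnot(length(dose_range) == 2L, all(dose_range > 0), dose_range[1] <= dose_range[2])
  }
  structure(
    list(n_freq = as.integer(n_freq), f_min = f_min, f_max = f_max,
         frequencies = freqs, transform = transform, dose_range = dose_range,
         sinusoidal = isTRUE(sinusoidal),
         dim = if (isTRUE(sinusoidal)) 2L * as.integer(n_freq) else 1L),
    class = "dose_embedder_config"
  )
}

#' @rdname dose_embedder_config
#' @param cfg A `dose_embedder_config`.
#' @param doses Positive numeric vector of training doses from which the
#'   min/max range is taken.
#' @export
set_dose_range <- function(cfg, doses) {
  stopifnot(inherits(cfg, "dose_embedder_config"), all(doses > 0))
  cfg$dose_range <- range(doses)
  cfg
}

# apply the configured dose transform; returns the scalar(s) fed to Eq-style
# sinusoids
transform_dose <- function(dose, cfg) {
  if (cfg$transform == "identity") return(dose)
  if (any(dose <= 0)) stop("doses must be strictly positive under the log transform", call. = FALSE)
  if (is.null(cfg$dose_range)) {
    stop("dose_range is not set; call set_dose_range() with the training doses",
         call. = FALSE)
  }
  lo <- log(cfg$dose_range[1L])
  hi <- log(cfg$dose_range[2L])
  if (hi - lo < .Machine$double.eps) return(rep(0.5, length(dose)))
  (log(dose) - lo) / (hi - lo)
}

#' Sinusoidal dose embedding
#'
#' @param dose Numeric vector of doses (strictly positive when the log
#'   transform is configured).
#' @param cfg A [dose_embedder_config()].
#' @return An `n x dim` numeric matrix, one embedded dose per row, columns
#'   interleaved as (sin f1, cos f1, sin f2, cos f2, ...).
#' @export
embed_dose <- function(dose, cfg) {
  stopifnot(inherits(cfg, "dose_embedder_config"), is.numeric(dose))
  if (any(!is.finite(dose))) stop("doses must be finite", call. = FALSE)
  d <- transform_dose(dose, cfg)
  if (!cfg$sinusoidal) return(matrix(d, ncol = 1L))
  ang <- outer(d, 2 * pi * cfg$frequencies)  # n x c
  out <- matrix(0, length(d), 2L * cfg$n_freq)
  out[, seq(1L, 2L * cfg$n_freq, by = 2L)] <- sin(ang)
  out[, seq(2L, 2L * cfg$n_freq, by = 2L)] <- cos(ang)
  out
}

## ---- drug 1D-CNN encoder ---------------------------------------------------

#' Configure the character-level 1D-CNN drug encoder
#'
#' Tokens are embedded into `embed_dim`-dimensional learned vectors (PAD is
#' pinned at zero), passed through stacked valid-mode 1D convolutions with
#' ReLU, global max-pooled over sequence positions, and projected linearly to
#' `out_dim`.
#'
#' @param embed_dim Token embedding width.
#' @param filters Integer vector, output channels per conv layer.
#' @param kernels Integer vector of kernel widths (same length as `filters`).
#' @param out_dim Drug embedding dimension.
#' @return An object of class `drug_encoder_config`.
#' @export
drug_encoder_config <- function(embed_dim = 16L, filters = c(32L, 64L),
                                kernels = c(5L, 5L), out_dim = 64L) {
  stopifnot(length(filters) == length(kernels), all(filters > 0), all(kernels > 0),
            embed_dim > 0, out_dim > 0)
  structure(list(embed_dim = as.integer(embed_dim), filters = as.integer(filters),
                 kernels = as.integer(kernels), out_dim = as.integer(out_dim)),
            class = "drug_encoder_config")
}

#' Initialize drug-encoder weights
#'
#' Draws He-scaled Gaussian weights from the current RNG stream; the PAD
#' embedding row is fixed at zero (and never updated), which makes the
#' encoder invariant to trailing padding.
#'
#' @param vocab A [smiles_vocabulary()].
#' @param cfg A [drug_encoder_config()].
#' @return Nested parameter list (`emb`, `conv`, `proj`).
#' @export
drug_encoder_init <- function(vocab, cfg) {
  stopifnot(inherits(vocab, "smiles_vocabulary"), inherits(cfg, "drug_encoder_config"))
  emb <- nn_mat(vocab$size, cfg$embed_dim)
  emb[vocab$pad + 1L, ] <- 0
  conv <- vector("list", length(cfg$filters))
  c_in <- cfg$embed_dim
  for (l in seq_along(cfg$filters)) {
    conv[[l]] <- list(W = nn_mat(cfg$kernels[l] * c_in, cfg$filters[l]),
                      b = numeric(cfg$filters[l]))
    c_in <- cfg$filters[l]
  }
  list(emb = emb,
       conv = conv,
       proj = list(W = nn_mat(c_in, cfg$out_dim), b = numeric(cfg$out_dim)))
}

# forward pass for one token sequence; keep = TRUE retains caches for backprop
drug_forward_one <- function(par, tokens, cfg, keep = FALSE) {
  H <- par$emb[tokens + 1L, , drop = FALSE]  # L x embed_dim
  caches <- if (keep) vector("list", length(cfg$filters))
  for (l in seq_along(cfg$filters)) {
    k <- cfg$kernels[l]
    if (nrow(H) < k) stop("sequence shorter than kernel width", call. = FALSE)
    P <- conv_patches(H, k)
    Z <- P %*% par$conv[[l]]$W
    Z <- Z + rep(par$conv[[l]]$b, each = nrow(Z))
    Hn <- relu(Z)
    if (keep) caches[[l]] <- list(P = P, H = Hn, L_in = nrow(H), C_in = ncol(H))
    H <- Hn
  }
  pool_idx <- max.col(t(H), ties.method = "first")
  pooled <- H[cbind(pool_idx, seq_len(ncol(H)))]
  out <- drop(crossprod(pooled, par$proj$W)) + par$proj$b
  if (keep) list(out = out, pooled = pooled, pool_idx = pool_idx,
                 caches = caches, last_dim = dim(H))
  else out
}

# forward a whole token matrix (n x L); returns n x out_dim matrix (+caches)
drug_forward_batch <- function(par, tokens_mat, cfg, keep = FALSE) {
  n <- nrow(tokens_mat)
  out <- matrix(0, n, cfg$out_dim)
  caches <- if (keep) vector("list", n)
  for (i in seq_len(n)) {
    fw <- drug_forward_one(par, tokens_mat[i, ], cfg, keep = keep)
    if (keep) {
      out[i, ] <- fw$out
      caches[[i]] <- fw
    } else out[i, ] <- fw
  }
  if (keep) list(out = out, caches = caches) else out
}

# backprop dOut (n x out_dim) through the batch; returns gradients shaped
# like the parameter list (PAD embedding gradient forced to zero)
drug_backward_batch <- function(par, tokens_mat, fw, dOut, cfg) {
  g <- zeros_like(par)
  for (i in seq_len(nrow(tokens_mat))) {
    ci <- fw$caches[[i]]
    di <- dOut[i, ]
    g$proj$W <- g$proj$W + outer(ci$pooled, di)
    g$proj$b <- g$proj$b + di
    dPool <- drop(par$proj$W %*% di)
    dH <- matrix(0, ci$last_dim[1L], ci$last_dim[2L])
    dH[cbind(ci$pool_idx, seq_len(ci$last_dim[2L]))] <- dPool
    for (l in rev(seq_along(cfg$filters))) {
      cc <- ci$caches[[l]]
      dZ <- dH * relu_mask(cc$H)
      g$conv[[l]]$W <- g$conv[[l]]$W + crossprod(cc$P, dZ)
      g$conv[[l]]$b <- g$conv[[l]]$b + colSums(dZ)
      dP <- dZ %*% t(par$conv[[l]]$W)
      dH <- conv_patches_backward(dP, cfg$kernels[l], cc$L_in, cc$C_in)
    }
    tok <- tokens_mat[i, ] + 1L
    for (p in seq_along(tok)) g$emb[tok[p], ] <- g$emb[tok[p], ] + dH[p, ]
  }
  g$emb[1L, ] <- 0  # PAD row stays pinned
  g
}

#' Encode a tokenized drug
#'
#' Deterministic forward pass of the 1D-CNN drug encoder for fixed weights.
#'
#' @param tokens Integer vector from [tokenize_smiles()] (length
#'   `vocab$max_length`).
#' @param params Weights from [drug_encoder_init()] (or trained weights).
#' @param cfg The matching [drug_encoder_config()].
#' @return Numeric embedding vector of length `cfg$out_dim`.
#' @export
encode_drug <- function(tokens, params, cfg) {
  stopifnot(inherits(cfg, "drug_encoder_config"))
  if (max(tokens) + 1L > nrow(params$emb)) {
    stop("token index exceeds embedding table size", call. = FALSE)
  }
  drug_forward_one(params, as.integer(tokens), cfg)
}

## ---- cell-line MLP encoder -------------------------------------------------

#' Configure the cell-line expression encoder
#'
#' Exactly three fully connected layers (a fixed architectural choice of the
#' model): input -> `hidden[1]` -> `hidden[2]` -> `out_dim`, each followed by
#' ReLU except the last, whose activation is configurable.
#'
#' @param hidden Two positive integers, the widths of the first two layers.
#' @param out_dim Cell embedding dimension (third-layer width).
#' @param final_activation `"relu"` (default) or `"identity"`.
#' @return An object of class `cell_encoder_config`.
#' @export
cell_encoder_config <- function(hidden = c(128L, 64L), out_dim = 32L,
                                final_activation = c("relu", "identity")) {
  stopifnot(length(hidden) == 2L, all(hidden > 0), out_dim > 0)
  structure(list(hidden = as.integer(hidden), out_dim = as.integer(out_dim),
                 final_activation = match.arg(final_activation)),
            class = "cell_encoder_config")
}

#' @rdname cell_encoder_config
#' @param n_genes Expression profile length (input dimension).
#' @param cfg A `cell_encoder_config`.
#' @export
cell_encoder_init <- function(n_genes, cfg) {
  stopifnot(inherits(cfg, "cell_encoder_config"), n_genes > 0)
  mlp_init(c(n_genes, cfg$hidden, cfg$out_dim))
}

#' Encode a cell-line expression profile
#'
#' @param profile Numeric vector (one profile) or matrix (profiles in rows).
#' @param params Weights from [cell_encoder_init()].
#' @param cfg The matching [cell_encoder_config()].
#' @return Embedding vector, or matrix with one embedding per row.
#' @export
encode_cell_line <- function(profile, params, cfg) {
  stopifnot(inherits(cfg, "cell_encoder_config"))
  X <- if (is.matrix(profile)) profile else matrix(profile, nrow = 1L)
  if (ncol(X) != nrow(params$W[[1L]])) {
    stop("profile length ", ncol(X), " does not match encoder input dimension ",
         nrow(params$W[[1L]]), call. = FALSE)
  }
  out <- mlp_forward(params, X, act = "relu", out_act = cfg$final_activation)$out
  if (is.matrix(profile)) out else drop(out)
}

## ---- joint feature ---------------------------------------------------------

#' Concatenate the five embeddings into the joint feature vector
#'
#' Fixed order: drug-1 embedding, drug-2 embedding, dose-1 embedding,
#' dose-2 embedding, cell embedding. This is the input of both the synergy
#' head and the per-query graph nodes.
#'
#' @param d1,d2 Drug embedding vectors (or matrices, rows aligned).
#' @param r1,r2 Dose embedding vectors/matrices.
#' @param cell Cell embedding vector/matrix.
#' @return Concatenated vector, or row-wise concatenated matrix.
#' @export
build_joint_feature <- function(d1, d2, r1, r2, cell) {
  parts <- list(d1, d2, r1, r2, cell)
  if (any(vapply(parts, is.matrix, logical(1L)))) {
    parts <- lapply(parts, function(p) if (is.matrix(p)) p else matrix(p, nrow = 1L))
    do.call(cbind, parts)
  } else {
    c(d1, d2, r1, r2, cell)
  }
}
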