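#' Generate a reproducible set of random PWMs
#'
#' Columns are drawn i.i.d. from a symmetric Dirichlet with the given
#' concentration (small values give sharp, TF-like columns; large values
#' approach uniform columns with total information content near 0); widths
#' are uniform over `width`. The same seed always regenerates the identical
#' set, and the caller's RNG state is left untouched.
#'
#' @param n_motifs Number of motifs.
#' @param width Length-2 integer range of motif widths (inclusive), or a
#'   single fixed width.
#' @param concentration Dirichlet concentration parameter (default 0.5).
#' @param alphabet Motif alphabet.
#' @param seed Integer seed; required, so fixtures are deterministic.
#' @param name_prefix Motif names are `<prefix>_1 ... <prefix>_n`.
#' @return A [motif_set()] of frequency motifs.
#' @export
random_pwm_set <- function(n_motifs, width = c(8L, 12L), concentration = 0.5,
                           alphabet = c("A", "C", "G", "T"), seed,
                           name_prefix = "motif") {
  if (length(width) == 1) width <- c(width, width)
  if (width[1] < 1 || width[2] < width[1]) {
    rlang::abort("Invalid width range.", class = "ttl_value_error")
  }
  A <- length(alphabet)
  motifs <- with_seed(seed, lapply(seq_len(n_motifs), function(k) {
    w <- sample_range(width[1], width[2])
    motif(paste0(name_prefix, "_", k), rdirichlet_cols(A, w, concentration),
      alphabet = alphabet, semantics = "frequency"
    )
  }))
  motif_set(motifs, source = sprintf("random_pwm_set(seed = %d)", seed))
}

# uniform draw from lo:hi that is safe when lo == hi (sample() would
# otherwise treat the scalar as 1:n)
sample_range <- function(lo, hi) {
  if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# i.i.d. Dirichlet(conc) columns via normalised gammas
rdirichlet_cols <- function(A, w, concentration) {
  g <- matrix(stats::rgamma(A * w, shape = concentration), nrow = A)
  cs <- colSums(g)
  zero <- cs == 0 # gamma draws can underflow at tiny concentrations
  if (any(zero)) {
    g[, zero] <- 1
    cs[zero] <- A
  }
  sweep(g, 2, cs, "/")
}

# evaluate code under a fixed seed, restoring any prior RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a planted-truth seqlet annotation scenario
#'
#' Builds a random motif database, then a seqlet set consisting of
#' shifted / reverse-complemented / noised copies of randomly chosen database
#' motifs plus pure-noise decoys, together with a truth table recording each
#' seqlet's source. Shifting embeds the copy between random flanking columns
#' (`shift` extra columns split at random between the two sides); noise mixes
#' each column with the uniform column at rate `noise`. Fully deterministic
#' from `seed`.
#'
#' @param n_database Database size.
#' @param n_seqlets Number of planted seqlet copies.
#' @param n_decoys Number of pure-noise decoy seqlets.
#' @param width Width range of database motifs (and decoys).
#' @param concentration Dirichlet concentration of generated columns.
#' @param max_shift Maximum number of flanking columns added to a copy; must
#'   be smaller than the minimum motif width.
#' @param rc_prob Probability a planted copy is reverse complemented.
#' @param noise Uniform-mixing rate in `[0, 1]` applied to planted columns.
#' @param seed Integer seed.
#' @param alphabet Motif alphabet (4 letters when `rc_prob > 0`).
#' @return List with `seqlets` and `database` ([motif_set()]s) and `truth`, a
#'   tibble with one row per *planted* seqlet (`seqlet`, `source`, `shift`,
#'   `orientation`, `noise`); decoys carry a `decoy_` name prefix and no
#'   truth row.
#' @export
planted_database <- function(n_database = 50, n_seqlets = 20, n_decoys = 5,
                             width = c(8L, 12L), concentration = 0.5,
                             max_shift = 0L, rc_prob = 0, noise = 0, seed,
                             alphabet = c("A", "C", "G", "T")) {
  if (max_shift >= width[1]) {
    rlang::abort("max_shift must be smaller than the minimum motif width.",
      class = "ttl_value_error"
    )
  }
  database <- random_pwm_set(n_database,
    width = width, concentration = concentration,
    alphabet = alphabet, seed = seed, name_prefix = "db"
  )
  A <- length(alphabet)
  out <- with_seed(seed + 1L, {
    seqlets <- list()
    truth <- vector("list", n_seqlets) # planted copies only; decoys have no source
  for (k in seq_len(n_seqlets)) {
    src <- sample(names(database$motifs), 1)
    mat <- database$motifs[[src]]$matrix
    shift <- if (max_shift > 0) sample_range(0L, max_shift) else 0L
    left <- if (shift > 0) sample_range(0L, shift) else 0L
    if (left > 0) mat <- cbind(rdirichlet_cols(A, left, concentration), mat)
    if (shift - left > 0) mat <- cbind(mat, rdirichlet_cols(A, shift - left, concentration))
    orientation <- if (stats::runif(1) < rc_prob) "-" else "+"
    if (orientation == "-") mat <- rc_matrix(mat)
    if (noise > 0) mat <- (1 - noise) * mat + noise / A
    seqlets[[k]] <- motif(paste0("seqlet_", k), mat, alphabet = alphabet)
    truth[[k]] <- tibble::tibble(
      seqlet = paste0("seqlet_", k), source = src,
      shift = shift, orientation = orientation, noise = noise
    )
  }
  for (k in seq_len(n_decoys)) {
    w <- sample_range(width[1], width[2])
    seqlets[[n_seqlets + k]] <- motif(
      paste0("decoy_", k), rdirichlet_cols(A, w, concentration),
      alphabet = alphabet
    )
  }
    list(seqlets = seqlets, truth = truth)
  })
  list(
    seqlets = motif_set(out$seqlets, source = sprintf("planted_database(seed = %d)", seed)),
    database = database,
    truth = dplyr::bind_rows(out$truth)
  )
}
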