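# Random valid stream messages, used by the protocol round-trip tests.
# Ids are distinct within one batch so the create-before-update ordering
# invariant holds by construction.
random_messages <- function(n, start_id = 1L) {
  msgs <- list()
  id <- start_id
  for (i in seq_len(n)) {
    type <- sample(c("tumor_cell", "endothelial_cell"), 1)
    msgs[[i]] <- anim_message(
      sample(c("create", "update"), 1), id = id, type = type,
      voxel = sample.int(40, 3, replace = TRUE),
      state = if (type == "tumor_cell") {
        sample(c("proliferating", "quiescent", "hypoxic", "necrotic"), 1)
      } else {
        sample(c("stalk", "tip"), 1)
      },
      pred = if (type == "endothelial_cell") {
        if (runif(1) < 0.2) NA_integer_ else sample.int(1000, 1)
      } else NULL)
    id <- id + 1L
  }
  msgs
}
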