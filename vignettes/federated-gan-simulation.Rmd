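---
title: "Simulating cross-silo federated DCGAN training for medical image synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cross-silo federated DCGAN training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silogan)
```

## The problem

Medical imaging datasets are siloed in institutions that cannot pool raw
data. One route around this is to train a *generative* model federatively:
each clinic trains a deep convolutional GAN (DCGAN) locally, a coordinating
server averages the weights (FedAvg), and only the synthetic images — never
patient data — leave the federation. `silogan` simulates this whole workflow
in a single R process: preprocessing, label-skew partitioning across
simulated clinics, transfer pretraining on a second imaging domain,
round-based adversarial training with weighted aggregation, quality
evaluation, and a privacy-leakage audit of the trained generator.

The intended application pattern is severity-graded retinal fundus imaging
(grades 0 = healthy to 4 = severe) fine-tuned from a generator pretrained on
morphologically different abdominal CT slices. Because those corpora cannot
ship with a package, `silogan` includes a phantom generator that emulates
the *statistical structure* the framework depends on, so every stage runs
end-to-end without downloads.

## The model

### Adversarial objective

A generator $G$ maps latent noise $z \sim \mathcal N(0, I_{200})$ to a
single-channel image; a discriminator $D$ scores images as real. The
classical minimax objective is

$$\min_G \max_D V(D, G) =
  \mathbb E_{x \sim p_\text{data}}[\log D(x)] +
  \mathbb E_{z \sim p_z}[\log(1 - D(G(z)))].$$

Training uses the standard practical surrogates: the discriminator minimizes
binary cross-entropy with a *smoothed* real target of 0.9 (tempering
overconfidence and preserving generator gradients),

$$L_D = -\mathbb E_x[0.9 \log D(x) + 0.1 \log(1 - D(x))]
        -\mathbb E_z[\log(1 - D(G(z)))],$$

and the generator minimizes the non-saturating form
$L_G = -\mathbb E_z[\log D(G(z))]$ rather than the saturating
$\log(1 - D(G(z)))$ of the minimax display — the non-saturating form has
the same fixed points but usable gradients early in training. With smoothing
disabled, $L_D = -V(D, G)$ exactly at the sampled probabilities; a test
asserts this consistency.

### Architecture

At the full 128 × 128 resolution the generator is: dense layer with 16384
units reshaped to 8 × 8 × 256, then four stride-2 transposed convolutions
(4 × 4 kernels) with 128, 64, 32, 1 filters; hidden blocks use batch
normalization and ReLU, the output block a tanh. The discriminator mirrors
it: four stride-2 convolutions (4 × 4) with 32, 64, 128, 256 filters,
LeakyReLU(0.2), batch normalization on blocks 2–4, then a dense unit with a
sigmoid. For smaller image sizes the 8 × 8 × 256 stem is retained and
blocks are dropped: the generator keeps the *last* `log2(size/8)` filter
counts (so the tanh output block always remains) and the discriminator the
*first* ones. At 16 × 16 — the size used throughout the test suite — the
generator therefore has a single (linear-before-tanh) upsampling block;
this is deliberate desk-scale frugality, documented here because it bounds
how much adversarial structure the smallest models can express.

Weights initialize as $\mathcal N(0, 0.02)$ (the DCGAN convention); both
networks train with Adam at learning rate $2\times 10^{-4}$, $\beta_1 =
0.5$, $\beta_2 = 0.999$, batch size 64, latent dimension 200.

The engine behind these models is written in-package on base matrix
algebra: batches are `(C*H*W) x B` matrices with channel-fastest layout, and
every (transposed) convolution is evaluated tap-by-tap — one gather, one
dense `OC x C` product, one scatter-add per kernel position — which keeps
peak memory near the activation size and routes the arithmetic through
BLAS. Gradients of every layer are verified against finite differences in
the test suite (relative error below $10^{-4}$ at probe points).

### Federated averaging

Clients $k = 1 \dots K$ each hold a shard $\mathcal D_k$. Every round the
server distributes the global weights, each client runs $E$ local epochs of
alternating D/G updates, and the server replaces both global networks with

$$\theta^{t+1} = \sum_{k=1}^K \frac{|\mathcal D_k|}{\sum_j |\mathcal D_j|}
  \,\theta_k^{t+1}.$$

`fedavg()` implements this as an exact elementwise convex combination
(weighted by shard sizes by default; a `uniform` mode is kept because plain
averaging is also a legitimate reading of round-based descriptions of the
procedure — the discrepancy is surfaced as configuration rather than
hidden). Batch-norm running statistics are part of the weight set and are
averaged with the same coefficients; this is the plain reading of
layer-wise averaging, and it keeps aggregation a single well-defined
operation. All $K$ clients participate every round (cross-silo setting).
Client $k$ in a round is seeded with `round_seed XOR k`, making the whole
experiment a deterministic function of `(seed, config)` on one thread.

### Non-IID partitioning

Clinics specialize; their label distributions differ. The partitioner
reproduces that: records are grouped by severity grade, each grade is
assigned to **two** clients drawn uniformly, and each record goes to one of
its grade's two holders with probability 1/2. A rebalancing pass then
enforces a floor of $T = \lceil 0.01\, n \rceil$ records per client by
repeatedly moving uniformly chosen records from the currently largest shard
to the currently smallest. Choices the procedure leaves open, fixed here:
$T$ uses the ceiling; ties at argmax/argmin break toward the lowest client
id; the batch moved per iteration is capped at `largest - T` so the donor
never drops below the floor, which also guarantees termination (if any
shard is below $T$ while all are $\le T$, the total would be below $K\,T$,
contradicting feasibility). Rebalancing may break the two-clients-per-label
property, so that invariant is asserted pre-rebalance only.

## Preprocessing

Raw images pass through, in order: resize to the target size (bilinear,
anti-aliased), grayscale (ITU-R BT.601 weights 0.299/0.587/0.114), CLAHE at
8 bits, normalization to $[0,1]$, gamma correction $x \mapsto x^\gamma$,
quantization to 16 gray levels, and rescaling $x \mapsto 2x - 1$. Defaults:
CLAHE clip limit 2.0 on an 8 × 8 tile grid, $\gamma = 1.2$ — common
practitioner defaults, configurable because the procedure itself does not
pin them down. Two conventions are fixed and tested explicitly:

* **CLAHE mapping**: per tile, the 256-bin histogram is clipped at
  `clip_limit * N/256`, the excess is redistributed uniformly, and the tile
  mapping is $m(v) = \operatorname{round}(\mathrm{cdf}(v)/N \cdot 255)$;
  pixels interpolate bilinearly between the four neighbouring tile-center
  mappings, so a pixel at a tile center receives exactly its own tile's
  mapping (the test anchor against a blockwise oracle).
* **Quantization tie-break**: round half *up*,
  $\lfloor x(n{-}1) + 0.5\rfloor/(n{-}1)$, so 0.5 at 16 levels maps to
  8/15.

Degenerate inputs (any side below 8 pixels, or constant intensity) are
logged and skipped rather than fatal, and the batch runner reports the
skip count. Processed images serialize to a length-prefixed binary record
stream (float32 pixels, optional label, source id) whose reader names the
byte offset of any parse failure; the round trip is float32-exact and
order-preserving.

Note that the full pipeline is *not* idempotent — CLAHE re-equalizes its
own output — so the tested reapplication property is the honest one:
quantization is a projection (applying it twice equals once) and the final
rescale is an exact bijection.

## The phantom generator

The synthetic-data module defines the study conditions; it is not a tuning
knob. Fundus-like phantoms are 8-bit images with a circular field of view
on a constant-zero exterior, a radial vignette, 2–4 vessel-like random-walk
curves, and a $\mathrm{Poisson}(\lambda(\ell))$ number of lesions for grade
$\ell$ — each independently a bright exudate-like disc or a dark
hemorrhage-like blob with radius uniform on 2–5 px at 128 × 128 (scaled
proportionally at other sizes). The default rate is $\lambda(\ell) =
3\ell$, so grade 0 has no lesions and expected counts increase strictly
with severity; both facts are Monte-Carlo-tested. CT-like phantoms are
elliptical body outlines with 3–6 interior organ-like ellipses and no
lesions. The two domains share low-level statistics (smooth grayscale
anatomy, dark background, central bright mass) but not high-level
structure, which is exactly the premise that makes transfer pretraining
from CT to fundus meaningful.

What the phantoms do *not* emulate: clinical texture, acquisition noise,
vendor variation, anatomical correctness. Passing tests demonstrate that
the machinery is correct and directionally sensible under the assumed
statistical structure — not that the framework reaches any particular
quality on real retinal data.

## Evaluation

* **Realism score**: the mean probability a *frozen* centrally trained
  discriminator assigns to 256 fixed-seed generator samples. The scorer is
  the discriminator of a non-federated baseline GAN trained on the full
  dataset and is never updated by federated rounds. Scores are computed on
  the mean sigmoid output (the post-sigmoid convention, fixed here because
  the convention is otherwise ambiguous) after each aggregation.
* **Fréchet distance**: $\lVert\mu_r - \mu_f\rVert^2 + \operatorname{Tr}
  (\Sigma_r + \Sigma_f - 2(\Sigma_r\Sigma_f)^{1/2})$ on embedded images,
  with sample moments, $10^{-6} I$ covariance regularization, the trace
  term via the symmetric eigendecomposition of
  $\Sigma_r^{1/2}\Sigma_f\Sigma_r^{1/2}$, and negative residuals above
  $-10^{-6}$ truncated to zero. Tests cross-check it against a direct
  eigendecomposition of the nonsymmetric product. The desk-scale embedder
  is a fixed-seed random-projection convolution (4 × 4, stride 2, ReLU,
  spatial mean per filter) — deterministic and download-free; any
  pretrained embedder can be substituted behind the same function
  contract for production use.
* **Loss variance**: per-configuration sample mean and standard deviation
  (n − 1 denominator) of loss series, for stability comparisons across
  client counts.

## Privacy audit

Four attacks against a trained generator and its training data, plus a
composite:

1. **Membership inference** trains a small convolutional classifier to
   separate real training images from generator outputs and reports
   held-out accuracy and AUC. This contrasts *training data vs synthetic
   data* — the framing used by the workflow this package reproduces — not
   the classic member-vs-non-member design; the caveat matters when
   comparing numbers across papers.
2. **Empirical epsilon** from the attack ROC:
   $\hat\varepsilon = \max_t \ln(\mathrm{TPR}_t / \mathrm{FPR}_t)$ with
   both rates floored at $1/n$. The one-sided form is used deliberately:
   it is the form consistent with the framework's stated single-threshold
   behaviour ($\hat\varepsilon(0.9, 0.45) = \ln 2$), whereas adding the
   complementary direction would yield $\ln(0.55/0.1) \approx 1.70$ at
   that point. Being a maximum statistic, $\hat\varepsilon$ is biased
   upward at finite sample sizes even for a powerless attack; the
   calibration test therefore compares the null value against the simulated
   chance-level distribution of the same statistic rather than against an
   exact zero.
3. **Model inversion** gradient-descends latent vectors (500 steps, step
   0.05, 5 random restarts by default — explicit configuration, since the
   procedure is otherwise unspecified) to minimize pixel MSE against each
   target; the best-so-far loss per kept trajectory is monotone by
   construction, and closed forms on a constant generator (zero loss for
   the emitted image, $\overline{4x_0^2}$ for its negation) anchor the
   implementation.
4. **Nearest-neighbour distances** between synthetic and real sets under
   per-pixel RMS in $[-1,1]$ space (size-independent by construction),
   checked against a brute-force double loop.

The composite risk score is the documented convex combination
$100\,[0.4\,\mathrm{AUC} + 0.2\,\mathrm{acc} + 0.2\,(1-\min(\mathrm{inv},1))
+ 0.2\,(1-\min(\bar d_{\min},1))]$, higher meaning more leakage. The
weights are explicit configuration; no claim is made that they reproduce
any published 0–100 scale.

## Problem sizes, numerics, and limitations

The test suite and the acceptance script run everything at 16 × 16 with a
few hundred phantoms, 3 clients, 2 rounds, 1 local epoch, and a 5-epoch
centralized baseline — sizes chosen so the full battery completes on a
laptop CPU in minutes while still exercising every code path, including
multi-block architectures at 32 × 32 and shape contracts up to 128.
Consequences worth knowing:

* After this little training the frozen scorer is barely discriminative,
  so realism scores cluster near 0.5 and the trained-vs-untrained and
  pretrained-vs-random comparisons are directional checks with small
  margins, stable only because every run is a deterministic function of
  its seed. Demonstrating *large* quality gaps requires GPU-scale training
  on real data, which is out of scope by design.
* Probabilities are clamped to $[10^{-7}, 1-10^{-7}]$ before logs; values
  outside $[0,1]$ are errors, not clamped.
* Batch-norm uses batch statistics during training and running statistics
  (momentum 0.9 — chosen over the common 0.99 so that running statistics
  are meaningful after desk-scale step counts) for evaluation and
  inversion; the generator's own single-image overfit behaviour is tested
  via its reconstruction error, because with both networks training from
  scratch the generator *loss* starts at $\ln 2$ against an uninformative
  discriminator and cannot be expected to decrease even as the fit
  improves.
* Adam state is reset at each local-training call, as in round-based
  federated practice; optimizer state is not aggregated.
* Determinism holds on a single thread with a fixed BLAS; run-to-run
  reproducibility across machines is expected within the same numerical
  library stack.

## A worked example

```{r example, eval = FALSE}
library(silogan)

# 1. two phantom domains, preprocessed at 16 x 16
fundus <- preprocess_dataset(
  make_dataset(phantom_config(192, 16, domain = "fundus", seed = 101)),
  pipeline_config(16))$images
ct <- preprocess_dataset(
  make_dataset(phantom_config(192, 16, domain = "ct", seed = 301)),
  pipeline_config(16))$images

# 2. federated fine-tuning with CT pretraining, 3 clients, 2 rounds
cfg <- federation_config(K = 3, rounds = 2, local_epochs = 1,
                         image_size = 16, seed = 1)
res <- run_experiment(3, fundus, pretrain_images = ct, cfg)
vapply(res$runs[["3"]]$rounds, function(r) r$realism, numeric(1))

# 3. privacy audit of the aggregated generator
privacy_audit(res$runs[["3"]]$G, fundus,
              attack_config(epochs = 15, inversion_steps = 100, seed = 1))
```

The same pipeline is available from a shell through the
`inst/cli/silogan` script (`make-synthetic`, `preprocess`, `partition`,
`pretrain`, `train-federated`, `evaluate`, `privacy-audit`, `report`),
each stage reading the previous stage's files and writing a JSON manifest
with output checksums.
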