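// Training and inference backend for the canonical digit CNN:
//   conv 3x3x32 -> maxpool 2x2 -> conv 3x3x64 -> maxpool 2x2 -> conv 3x3x64
//   -> flatten -> dense 64 (relu) -> dense 10 (softmax),
// valid convolutions, stride-1 conv / stride-2 pool, categorical
// cross-entropy, RMSprop. Feature maps are carried as (h*w) x depth
// matrices with pixel index p = r*w + c (row-major); the exported
// activation matrices use column-major vectorisation of those maps, i.e.
// feature index k = p + h*w*f, which the R wrappers reshape and document.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Patch-extraction for a 3x3 valid convolution. in: (h*w) x d. Output:
// (oh*ow) x 9d where the 9 kernel offsets (dr,dc) are laid out in blocks of
// d columns, row-major over the offsets.
mat im2col3(const mat& in, const int h, const int w) {
  const int d = in.n_cols;
  const int oh = h - 2, ow = w - 2;
  mat out(oh * ow, 9 * d);
  for (int dr = 0; dr < 3; ++dr) {
    for (int dc = 0; dc < 3; ++dc) {
      const int k = dr * 3 + dc;
      for (int r = 0; r < oh; ++r) {
        // source pixels (r+dr, dc..dc+ow-1) are contiguous rows of `in`
        out.submat(r * ow, k * d, r * ow + ow - 1, k * d + d - 1) =
            in.rows((r + dr) * w + dc, (r + dr) * w + dc + ow - 1);
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add patch gradients back onto the input map.
mat col2im3(const mat& cols, const int h, const int w, const int d) {
  const int oh = h - 2, ow = w - 2;
  mat out(h * w, d, fill::zeros);
  for (int dr = 0; dr < 3; ++dr) {
    for (int dc = 0; dc < 3; ++dc) {
      const int k = dr * 3 + dc;
      for (int r = 0; r < oh; ++r) {
        out.rows((r + dr) * w + dc, (r + dr) * w + dc + ow - 1) +=
            cols.submat(r * ow, k * d, r * ow + ow - 1, k * d + d - 1);
      }
    }
  }
  return out;
}

// 2x2 stride-2 max pooling with floor on odd sizes; records the winning
// source row per (output pixel, filter) for the backward pass.
mat maxpool2(const mat& in, const int h, const int w, umat& argmax) {
  const int d = in.n_cols;
  const int oh = h / 2, ow = w / 2;
  mat out(oh * ow, d);
  argmax.set_size(oh * ow, d);
  for (int r = 0; r < oh; ++r) {
    for (int c = 0; c < ow; ++c) {
      const int p = r * ow + c;
      const int s00 = (2 * r) * w + 2 * c;
      const int cand[4] = {s00, s00 + 1, s00 + w, s00 + w + 1};
      for (int f = 0; f < d; ++f) {
        double best = in(cand[0], f);
        int bi = cand[0];
        for (int j = 1; j < 4; ++j) {
          if (in(cand[j], f) > best) {
            best = in(cand[j], f);
            bi = cand[j];
          }
        }
        out(p, f) = best;
        argmax(p, f) = bi;
      }
    }
  }
  return out;
}

mat unpool2(const mat& grad, const umat& argmax, const int h, const int w,
            const int d) {
  mat out(h * w, d, fill::zeros);
  for (uword p = 0; p < grad.n_rows; ++p) {
    for (int f = 0; f < d; ++f) {
      out(argmax(p, f), f) += grad(p, f);
    }
  }
  return out;
}

struct Weights {
  mat W1, W2, W3, W4, W5;  // 27x32, 288x64, 576x64, 576x64, 64x10
  vec b1, b2, b3, b4, b5;
};

Weights weights_from_list(const Rcpp::List& w) {
  Weights out;
  out.W1 = Rcpp::as<mat>(w["W1"]);
  out.b1 = Rcpp::as<vec>(w["b1"]);
  out.W2 = Rcpp::as<mat>(w["W2"]);
  out.b2 = Rcpp::as<vec>(w["b2"]);
  out.W3 = Rcpp::as<mat>(w["W3"]);
  out.b3 = Rcpp::as<vec>(w["b3"]);
  out.W4 = Rcpp::as<mat>(w["W4"]);
  out.b4 = Rcpp::as<vec>(w["b4"]);
  out.W5 = Rcpp::as<mat>(w["W5"]);
  out.b5 = Rcpp::as<vec>(w["b5"]);
  return out;
}

Rcpp::List weights_to_list(const Weights& w) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = w.W1, Rcpp::Named("b1") = w.b1,
      Rcpp::Named("W2") = w.W2, Rcpp::Named("b2") = w.b2,
      Rcpp::Named("W3") = w.W3, Rcpp::Named("b3") = w.b3,
      Rcpp::Named("W4") = w.W4, Rcpp::Named("b4") = w.b4,
      Rcpp::Named("W5") = w.W5, Rcpp::Named("b5") = w.b5);
}

// Pull image i out of the (n, 28, 28, 3) R array into a 784 x 3 map with
// pixel index p = r*28 + c.
mat image_matrix(const Rcpp::NumericVector& X, const int n, const int i) {
  mat out(784, 3);
  for (int ch = 0; ch < 3; ++ch) {
    for (int r = 0; r < 28; ++r) {
      for (int c = 0; c < 28; ++c) {
        out(r * 28 + c, ch) = X[i + (R_xlen_t)n * (r + 28 * (c + 28 * ch))];
      }
    }
  }
  return out;
}

struct ForwardState {
  mat C1, Z1, A1, P1;  // im2col patches, pre/post relu, pooled
  umat am1;
  mat C2, Z2, A2, P2;
  umat am2;
  mat C3, Z3, A3;
  vec f, z4, a4, z5, p;
};

void forward_one(const mat& x0, const Weights& w, ForwardState& s) {
  s.C1 = im2col3(x0, 28, 28);                    // 676 x 27
  s.Z1 = s.C1 * w.W1;
  s.Z1.each_row() += w.b1.t();
  s.A1 = clamp(s.Z1, 0.0, datum::inf);           // relu, 676 x 32
  s.P1 = maxpool2(s.A1, 26, 26, s.am1);          // 169 x 32

  s.C2 = im2col3(s.P1, 13, 13);                  // 121 x 288
  s.Z2 = s.C2 * w.W2;
  s.Z2.each_row() += w.b2.t();
  s.A2 = clamp(s.Z2, 0.0, datum::inf);           // 121 x 64
  s.P2 = maxpool2(s.A2, 11, 11, s.am2);          // 25 x 64

  s.C3 = im2col3(s.P2, 5, 5);                    // 9 x 576
  s.Z3 = s.C3 * w.W3;
  s.Z3.each_row() += w.b3.t();
  s.A3 = clamp(s.Z3, 0.0, datum::inf);           // 9 x 64

  s.f = vectorise(s.A3);                         // 576
  s.z4 = w.W4.t() * s.f + w.b4;                  // 64
  s.a4 = clamp(s.z4, 0.0, datum::inf);
  s.z5 = w.W5.t() * s.a4 + w.b5;                 // 10
  const vec e = exp(s.z5 - s.z5.max());
  s.p = e / accu(e);
}

void backward_one(const mat& x0, const Weights& w, const ForwardState& s,
                  const int y, Weights& g) {
  vec dz5 = s.p;
  dz5(y) -= 1.0;
  g.W5 += s.a4 * dz5.t();
  g.b5 += dz5;
  vec dz4 = (w.W5 * dz5) % conv_to<vec>::from(s.z4 > 0);
  g.W4 += s.f * dz4.t();
  g.b4 += dz4;
  vec df = w.W4 * dz4;  // 576

  mat dZ3 = reshape(df, 9, 64) % conv_to<mat>::from(s.Z3 > 0);
  g.W3 += s.C3.t() * dZ3;
  g.b3 += sum(dZ3, 0).t();
  mat dP2 = col2im3(dZ3 * w.W3.t(), 5, 5, 64);   // 25 x 64

  mat dZ2 = unpool2(dP2, s.am2, 11, 11, 64) % conv_to<mat>::from(s.Z2 > 0);
  g.W2 += s.C2.t() * dZ2;
  g.b2 += sum(dZ2, 0).t();
  mat dP1 = col2im3(dZ2 * w.W2.t(), 13, 13, 32); // 169 x 32

  mat dZ1 = unpool2(dP1, s.am1, 26, 26, 32) % conv_to<mat>::from(s.Z1 > 0);
  g.W1 += s.C1.t() * dZ1;
  g.b1 += sum(dZ1, 0).t();
  (void)x0;
}

void rmsprop_step(mat& w, mat& cache, const mat& grad, const double lr,
                  const double rho, const double eps) {
  cache = rho * cache + (1.0 - rho) * square(grad);
  w -= lr * grad / (sqrt(cache) + eps);
}

void rmsprop_step(vec& w, vec& cache, const vec& grad, const double lr,
                  const double rho, const double eps) {
  cache = rho * cache + (1.0 - rho) * square(grad);
  w -= lr * grad / (sqrt(cache) + eps);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::NumericVector X, Rcpp::IntegerVector y,
                         Rcpp::List w0, Rcpp::IntegerMatrix orders,
                         int batch_size, double lr, double rho, double eps) {
  const Rcpp::IntegerVector dims = X.attr("dim");
  const int n = dims[0];
  const int epochs = orders.nrow();
  Weights w = weights_from_list(w0);
  Weights cache;
  cache.W1 = zeros(size(w.W1)); cache.b1 = zeros(size(w.b1));
  cache.W2 = zeros(size(w.W2)); cache.b2 = zeros(size(w.b2));
  cache.W3 = zeros(size(w.W3)); cache.b3 = zeros(size(w.b3));
  cache.W4 = zeros(size(w.W4)); cache.b4 = zeros(size(w.b4));
  cache.W5 = zeros(size(w.W5)); cache.b5 = zeros(size(w.b5));

  vec ep_loss(epochs), ep_acc(epochs);
  ForwardState s;

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    int correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n);
      const int bn = stop - start;
      Weights g;
      g.W1 = zeros(size(w.W1)); g.b1 = zeros(size(w.b1));
      g.W2 = zeros(size(w.W2)); g.b2 = zeros(size(w.b2));
      g.W3 = zeros(size(w.W3)); g.b3 = zeros(size(w.b3));
      g.W4 = zeros(size(w.W4)); g.b4 = zeros(size(w.b4));
      g.W5 = zeros(size(w.W5)); g.b5 = zeros(size(w.b5));
      for (int j = start; j < stop; ++j) {
        const int i = orders(ep, j) - 1;  // R indices are 1-based
        const mat x0 = image_matrix(X, n, i);
        forward_one(x0, w, s);
        const int yi = y[i];
        const double li = -std::log(std::max(s.p(yi), 1e-12));
        loss_sum += li;
        if (s.p.index_max() == (uword)yi) ++correct;
        backward_one(x0, w, s, yi, g);
      }
      const double scale = 1.0 / bn;
      rmsprop_step(w.W1, cache.W1, g.W1 * scale, lr, rho, eps);
      rmsprop_step(w.b1, cache.b1, g.b1 * scale, lr, rho, eps);
      rmsprop_step(w.W2, cache.W2, g.W2 * scale, lr, rho, eps);
      rmsprop_step(w.b2, cache.b2, g.b2 * scale, lr, rho, eps);
      rmsprop_step(w.W3, cache.W3, g.W3 * scale, lr, rho, eps);
      rmsprop_step(w.b3, cache.b3, g.b3 * scale, lr, rho, eps);
      rmsprop_step(w.W4, cache.W4, g.W4 * scale, lr, rho, eps);
      rmsprop_step(w.b4, cache.b4, g.b4 * scale, lr, rho, eps);
      rmsprop_step(w.W5, cache.W5, g.W5 * scale, lr, rho, eps);
      rmsprop_step(w.b5, cache.b5, g.b5 * scale, lr, rho, eps);
    }
    ep_loss(ep) = loss_sum / n;
    ep_acc(ep) = (double)correct / n;
    if (!std::isfinite(ep_loss(ep))) {
      Rcpp::stop("training diverged: non-finite loss at epoch %d", ep + 1);
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = weights_to_list(w),
      Rcpp::Named("loss") = ep_loss, Rcpp::Named("accuracy") = ep_acc);
}

// [[Rcpp::export]]
Rcpp::List cnn_forward_cpp(Rcpp::NumericVector X, Rcpp::List wlist,
                           bool activations) {
  const Rcpp::IntegerVector dims = X.attr("dim");
  const int n = dims[0];
  const Weights w = weights_from_list(wlist);
  mat probs(n, 10);
  mat A1, A2, A3;
  if (activations) {
    A1.set_size(n, 676 * 32);
    A2.set_size(n, 121 * 64);
    A3.set_size(n, 9 * 64);
  }
  ForwardState s;
  for (int i = 0; i < n; ++i) {
    const mat x0 = image_matrix(X, n, i);
    forward_one(x0, w, s);
    probs.row(i) = s.p.t();
    if (activations) {
      A1.row(i) = vectorise(s.A1).t();
      A2.row(i) = vectorise(s.A2).t();
      A3.row(i) = vectorise(s.A3).t();
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  if (activations) {
    return Rcpp::List::create(
        Rcpp::Named("probs") = probs, Rcpp::Named("A1") = A1,
        Rcpp::Named("A2") = A2, Rcpp::Named("A3") = A3);
  }
  return Rcpp::List::create(Rcpp::Named("probs") = probs);
}
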