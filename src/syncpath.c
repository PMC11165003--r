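/* Compiled right-hand sides for deSolve: variational (Master Stability
 * Function) equations of the built-in systems, Benettin renormalization
 * event functions, and the coupled-network flow.
 *
 * Variational state layout (3-dimensional flows):
 *   y[0..2] = base state x_s(t), y[3..5] = tangent vector eta,
 *   y[6]    = accumulated log of renormalization factors (zero derivative;
 *             incremented by the event function).
 * The linear test system (m = 1) uses y[0] = x, y[1] = eta, y[2] = acc.
 *
 * Network state layout: node-major, y[3*i + c] = component c of node i
 * (m = 1 for the linear system).  The Laplacian, coupling strength and
 * per-node parameters are installed by C_net_setup() before each ode()
 * call; deSolve then invokes derivs_net without an initializer.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <string.h>

/* ---------- variational equations ---------- */

static double var_p[4]; /* nu, p1, p2, p3 */

void initmod_var(void (*odeparms)(int *, double *))
{
    int n = 4;
    odeparms(&n, var_p);
}

/* Roessler (-y-z, x+a*y, b+z*(x-c)), output g(x) = (0, y, 0) */
void derivs_rossler_var(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    double nu = var_p[0], a = var_p[1], b = var_p[2], c = var_p[3];
    double x = y[0], yy = y[1], z = y[2];
    ydot[0] = -yy - z;
    ydot[1] = x + a * yy;
    ydot[2] = b + z * (x - c);
    /* eta' = [Jf(x_s) - nu Jg] eta, Jg = diag(0, 1, 0) */
    ydot[3] = -y[4] - y[5];
    ydot[4] = y[3] + (a - nu) * y[4];
    ydot[5] = z * y[3] + (x - c) * y[5];
    ydot[6] = 0.0;
}

/* Lorenz (sigma*(y-x), x*(rho-z)-y, x*y-beta*z), output g(x) = (x, 0, 0) */
void derivs_lorenz_var(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double nu = var_p[0], sigma = var_p[1], rho = var_p[2], beta = var_p[3];
    double x = y[0], yy = y[1], z = y[2];
    ydot[0] = sigma * (yy - x);
    ydot[1] = x * (rho - z) - yy;
    ydot[2] = x * yy - beta * z;
    /* Jg = diag(1, 0, 0) */
    ydot[3] = -sigma * y[3] + sigma * y[4] - nu * y[3];
    ydot[4] = (rho - z) * y[3] - y[4] - x * y[5];
    ydot[5] = yy * y[3] + x * y[4] - beta * y[5];
    ydot[6] = 0.0;
}

/* linear test system f(x) = x, g(x) = x (m = 1): Lambda(nu) = 1 - nu */
void derivs_linear_var(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double nu = var_p[0];
    ydot[0] = y[0];
    ydot[1] = (1.0 - nu) * y[1];
    ydot[2] = 0.0;
}

/* Benettin renormalization events: accumulate log|eta| and rescale. */
void event_renorm3(int *n, double *t, double *y)
{
    double nrm = sqrt(y[3] * y[3] + y[4] * y[4] + y[5] * y[5]);
    y[6] += log(nrm);
    y[3] /= nrm;
    y[4] /= nrm;
    y[5] /= nrm;
}

void event_renorm1(int *n, double *t, double *y)
{
    double nrm = fabs(y[1]);
    y[2] += log(nrm);
    y[1] /= nrm;
}

/* ---------- coupled network ---------- */

static int net_sysid = 0;   /* 1 roessler, 2 lorenz, 3 linear */
static int net_N = 0;
static double net_d = 0.0;
static double *net_L = NULL;    /* N x N Laplacian, column-major */
static double *net_P = NULL;    /* 3 x N per-node parameters */
static double *net_buf = NULL;  /* scratch: g-component and L %*% g */

SEXP C_net_setup(SEXP sysid, SEXP d, SEXP L, SEXP P)
{
    int N = (int)sqrt((double)Rf_xlength(L));
    if ((R_xlen_t)N * N != Rf_xlength(L))
        Rf_error("Laplacian must be square");
    if (net_L) { R_Free(net_L); net_L = NULL; }
    if (net_P) { R_Free(net_P); net_P = NULL; }
    if (net_buf) { R_Free(net_buf); net_buf = NULL; }
    net_sysid = Rf_asInteger(sysid);
    net_N = N;
    net_d = Rf_asReal(d);
    net_L = R_Calloc((size_t)N * N, double);
    net_P = R_Calloc((size_t)3 * N, double);
    net_buf = R_Calloc((size_t)2 * N, double);
    memcpy(net_L, REAL(L), sizeof(double) * (size_t)N * N);
    if (Rf_xlength(P) != (R_xlen_t)3 * N)
        Rf_error("parameter matrix must be 3 x N");
    memcpy(net_P, REAL(P), sizeof(double) * (size_t)3 * N);
    return R_NilValue;
}

void derivs_net(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int N = net_N, i, j;
    double *g = net_buf, *coup = net_buf + N;

    if (net_sysid == 3) {           /* linear, m = 1, g(x) = x */
        for (i = 0; i < N; i++) g[i] = y[i];
        for (i = 0; i < N; i++) coup[i] = 0.0;
        for (j = 0; j < N; j++) {
            double gj = g[j];
            const double *col = net_L + (size_t)j * N;
            for (i = 0; i < N; i++) coup[i] += col[i] * gj;
        }
        for (i = 0; i < N; i++) ydot[i] = y[i] - net_d * coup[i];
        return;
    }

    /* m = 3 flows; coupled component: Roessler y (1), Lorenz x (0) */
    int cc = (net_sysid == 1) ? 1 : 0;
    for (i = 0; i < N; i++) g[i] = y[3 * i + cc];
    for (i = 0; i < N; i++) coup[i] = 0.0;
    for (j = 0; j < N; j++) {
        double gj = g[j];
        const double *col = net_L + (size_t)j * N;
        for (i = 0; i < N; i++) coup[i] += col[i] * gj;
    }
    for (i = 0; i < N; i++) {
        double x = y[3 * i], yy = y[3 * i + 1], z = y[3 * i + 2];
        double p1 = net_P[3 * i], p2 = net_P[3 * i + 1], p3 = net_P[3 * i + 2];
        if (net_sysid == 1) {       /* Roessler a, b, c */
            ydot[3 * i] = -yy - z;
            ydot[3 * i + 1] = x + p1 * yy - net_d * coup[i];
            ydot[3 * i + 2] = p2 + z * (x - p3);
        } else {                    /* Lorenz sigma, rho, beta */
            ydot[3 * i] = p1 * (yy - x) - net_d * coup[i];
            ydot[3 * i + 1] = x * (p2 - z) - yy;
            ydot[3 * i + 2] = x * yy - p3 * z;
        }
    }
}
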