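// Discrete-event engine for one clinic session.
//
// All booked patients are present at session start (t = 0). Each patient
// works through an ordered remaining activity sequence. Every activity
// seizes one room of its type plus eligible staff; mammogram and ultrasound
// run as an atomic prep -> imaging subprocess in which the room is seized at
// prep start and held until imaging ends (a patient is only picked up for
// prep once an imaging room is free). Queues are FIFO with head-of-line
// blocking. New activities may start up to the close instant; an activity
// (or subprocess) in progress always completes. Patients still queued at
// close leave with their remaining sequence as overspill.
//
// Staff availability is thinned capacity: after serving for d minutes a
// server is blocked for d * (1 - a) / a minutes ("other duties"), so a role
// with n rostered staff supplies n * a effective servers.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
using namespace Rcpp;

namespace {

const int ACT_IA = 1, ACT_MAM = 2, ACT_US = 3, ACT_BIOPSY = 4;
// roles (0-based): 0 consultant, 1 NP, 2 PA, 3 band7 sono, 4 band6 sono,
// 5 band6 non-sono, 6 grade2 assistant
const int N_ROLES = 7;

// seize preference orders: least specialised staff first, to conserve
// consultants for biopsy and sonographers for ultrasound
const std::vector<int> PREF_IA = {1, 2, 0};
const std::vector<int> PREF_MAM = {5, 4, 3};
const std::vector<int> PREF_US = {4, 3};
const std::vector<int> PREF_PREP = {6, 5, 4};
const std::vector<int> PREF_BIOPSY_ASSIST = {6, 5, 4};

struct Ev {
  double t;
  int type; // 0 = activity/imaging end, 1 = prep end, 2 = server free tick,
            // 3 = patient arrival (staggered appointment time)
  int pid;
  long seqno; // tie-break: FIFO event processing at equal times
};
struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.seqno > b.seqno;
  }
};

struct Engine {
  // configuration
  double close;
  IntegerVector rooms; // 4 room counts, index act-1
  std::vector<std::vector<double>> free_at; // per role, per server
  std::vector<double> cool; // (1-a)/a per role
  double d_ia, d_mam, d_us, disp, prep, bio_lo, bio_hi, bio_p_long;

  // patient state
  std::vector<std::vector<int>> seqs;
  std::vector<int> pos;              // next activity index
  std::vector<double> act_start;     // start of current stage
  std::vector<double> sub_start;     // start of current subprocess (prep)
  std::vector<int> staff_role1, staff_srv1, staff_role2, staff_srv2;
  std::vector<double> finish; // completion time, NA if not completed
  std::vector<bool> done;

  // queues
  std::deque<int> q_act[5];   // per activity code 1..4
  std::deque<int> img_wait[5]; // post-prep, awaiting imaging staff (2,3)
  int room_in_use[5];

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> pq;
  long evseq = 0;

  // log
  std::vector<int> log_pid, log_act;
  std::vector<double> log_start, log_end;

  void push_ev(double t, int type, int pid) {
    pq.push(Ev{t, type, pid, evseq++});
  }

  double rtri(double m) {
    if (disp <= 0) return m;
    double a = m * (1 - disp), b = m * (1 + disp);
    double u = R::runif(0, 1);
    if (u < 0.5) return a + (b - a) * std::sqrt(u / 2);
    return b - (b - a) * std::sqrt((1 - u) / 2);
  }
  double sample_dur(int act) {
    switch (act) {
      case ACT_IA: return rtri(d_ia);
      case ACT_MAM: return rtri(d_mam);
      case ACT_US: return rtri(d_us);
      default: return R::runif(0, 1) < bio_p_long ? bio_hi : bio_lo;
    }
  }

  // find a free server among eligible roles (preference order); -1 if none
  bool find_staff(const std::vector<int>& pref, double t, int& role,
                  int& srv) {
    for (int r : pref) {
      for (size_t j = 0; j < free_at[r].size(); ++j) {
        if (free_at[r][j] <= t + 1e-9) {
          role = r;
          srv = (int)j;
          return true;
        }
      }
    }
    return false;
  }
  void seize(int role, int srv) { free_at[role][srv] = R_PosInf; }
  void release(int role, int srv, double t, double busy) {
    double until = t + busy * cool[role];
    free_at[role][srv] = until;
    if (until > t + 1e-9) push_ev(until, 2, -1);
  }

  int next_act(int pid) { return seqs[pid][pos[pid]]; }

  void start_single(int pid, int act, double t) {
    // IA or biopsy: room + staff for the whole duration
    room_in_use[act]++;
    double d = sample_dur(act);
    act_start[pid] = t;
    sub_start[pid] = t;
    push_ev(t + d, 0, pid);
  }

  void finish_activity(int pid, int act, double t) {
    log_pid.push_back(pid);
    log_act.push_back(act);
    log_start.push_back(sub_start[pid]);
    log_end.push_back(t);
    pos[pid]++;
    if (pos[pid] >= (int)seqs[pid].size()) {
      done[pid] = true;
      finish[pid] = t;
    } else {
      q_act[next_act(pid)].push_back(pid);
    }
  }

  bool try_starts(double t) {
    bool any = false, progress = true;
    bool allow_new = (t <= close + 1e-9);
    while (progress) {
      progress = false;
      // imaging stage for prepped patients (always allowed: subprocess is
      // atomic, room already held)
      for (int act : {ACT_US, ACT_MAM}) {
        while (!img_wait[act].empty()) {
          int pid = img_wait[act].front();
          int role, srv;
          const std::vector<int>& pref =
              (act == ACT_US) ? PREF_US : PREF_MAM;
          if (!find_staff(pref, t, role, srv)) break;
          seize(role, srv);
          img_wait[act].pop_front();
          staff_role1[pid] = role;
          staff_srv1[pid] = srv;
          double d = sample_dur(act);
          act_start[pid] = t;
          push_ev(t + d, 0, pid);
          progress = any = true;
        }
      }
      if (allow_new) {
        // biopsy: room + consultant + assistant
        while (!q_act[ACT_BIOPSY].empty()) {
          if (room_in_use[ACT_BIOPSY] >= rooms[ACT_BIOPSY - 1]) break;
          int pid = q_act[ACT_BIOPSY].front();
          int r1, s1, r2, s2;
          if (!find_staff({0}, t, r1, s1)) break;
          seize(r1, s1); // hold while probing the assistant
          if (!find_staff(PREF_BIOPSY_ASSIST, t, r2, s2)) {
            free_at[r1][s1] = t; // give the consultant back
            break;
          }
          seize(r2, s2);
          q_act[ACT_BIOPSY].pop_front();
          staff_role1[pid] = r1;
          staff_srv1[pid] = s1;
          staff_role2[pid] = r2;
          staff_srv2[pid] = s2;
          start_single(pid, ACT_BIOPSY, t);
          progress = any = true;
        }
        // imaging prep: room (held through imaging) + prep staff
        for (int act : {ACT_US, ACT_MAM}) {
          while (!q_act[act].empty()) {
            if (room_in_use[act] >= rooms[act - 1]) break;
            int pid = q_act[act].front();
            int role, srv;
            if (!find_staff(PREF_PREP, t, role, srv)) break;
            seize(role, srv);
            q_act[act].pop_front();
            room_in_use[act]++;
            staff_role1[pid] = role;
            staff_srv1[pid] = srv;
            sub_start[pid] = t;
            act_start[pid] = t;
            if (prep > 0) {
              push_ev(t + prep, 1, pid);
            } else {
              push_ev(t, 1, pid);
            }
            progress = any = true;
          }
        }
        // initial assessment: room + surgical staff
        while (!q_act[ACT_IA].empty()) {
          if (room_in_use[ACT_IA] >= rooms[ACT_IA - 1]) break;
          int pid = q_act[ACT_IA].front();
          int role, srv;
          if (!find_staff(PREF_IA, t, role, srv)) break;
          seize(role, srv);
          q_act[ACT_IA].pop_front();
          staff_role1[pid] = role;
          staff_srv1[pid] = srv;
          start_single(pid, ACT_IA, t);
          progress = any = true;
        }
      }
    }
    return any;
  }

  void handle(const Ev& ev) {
    double t = ev.t;
    if (ev.type == 2) return; // tick: try_starts runs after the batch
    int pid = ev.pid;
    if (ev.type == 3) { // arrival: join the queue for the first activity
      q_act[next_act(pid)].push_back(pid);
      return;
    }
    int act = next_act(pid);
    if (ev.type == 1) {
      // prep done: release prep staff, await imaging staff (room held)
      release(staff_role1[pid], staff_srv1[pid], t, t - sub_start[pid]);
      img_wait[act].push_back(pid);
      return;
    }
    // activity end
    release(staff_role1[pid], staff_srv1[pid], t, t - act_start[pid]);
    if (act == ACT_BIOPSY) {
      release(staff_role2[pid], staff_srv2[pid], t, t - act_start[pid]);
    }
    room_in_use[act]--;
    finish_activity(pid, act, t);
  }
};

} // namespace

// [[Rcpp::export(name = ".run_session_engine")]]
List run_session_engine(List patient_seqs, IntegerVector patient_pos,
                        NumericVector ready_time, IntegerVector rooms,
                        IntegerVector staff_counts,
                        NumericVector staff_avail, double close,
                        List duration_pars) {
  int n = patient_seqs.size();
  Engine e;
  e.close = close;
  e.rooms = rooms;
  e.d_ia = as<double>(duration_pars["initial_assessment"]);
  e.d_mam = as<double>(duration_pars["mammogram"]);
  e.d_us = as<double>(duration_pars["ultrasound"]);
  e.disp = as<double>(duration_pars["dispersion"]);
  e.prep = as<double>(duration_pars["prep"]);
  NumericVector bio = duration_pars["biopsy"];
  e.bio_lo = bio[0];
  e.bio_hi = bio[1];
  e.bio_p_long = as<double>(duration_pars["biopsy_long_prob"]);

  e.free_at.resize(N_ROLES);
  e.cool.resize(N_ROLES);
  for (int r = 0; r < N_ROLES; ++r) {
    e.free_at[r].assign(staff_counts[r], 0.0);
    double a = staff_avail[r];
    e.cool[r] = (1 - a) / a;
  }
  for (int a = 0; a < 5; ++a) e.room_in_use[a] = 0;

  e.seqs.resize(n);
  e.pos.assign(n, 0);
  e.act_start.assign(n, 0.0);
  e.sub_start.assign(n, 0.0);
  e.staff_role1.assign(n, -1);
  e.staff_srv1.assign(n, -1);
  e.staff_role2.assign(n, -1);
  e.staff_srv2.assign(n, -1);
  e.finish.assign(n, NA_REAL);
  e.done.assign(n, false);

  for (int i = 0; i < n; ++i) {
    IntegerVector s = patient_seqs[i];
    e.seqs[i] = std::vector<int>(s.begin(), s.end());
    e.pos[i] = patient_pos[i];
    if (e.pos[i] >= (int)e.seqs[i].size()) {
      e.done[i] = true; // defensive: nothing left to do
      e.finish[i] = 0.0;
    } else if (ready_time[i] <= 0) {
      e.q_act[e.seqs[i][e.pos[i]]].push_back(i);
    } else {
      e.push_ev(ready_time[i], 3, i);
    }
  }

  e.try_starts(0.0);
  while (!e.pq.empty()) {
    double t = e.pq.top().t;
    while (!e.pq.empty() && e.pq.top().t <= t + 1e-9) {
      Ev ev = e.pq.top();
      e.pq.pop();
      e.handle(ev);
    }
    e.try_starts(t);
  }

  // collect overspill: anyone not done keeps their remaining sequence
  List remaining(n);
  LogicalVector completed(n);
  NumericVector fin(n);
  IntegerVector completed_acts(n);
  for (int i = 0; i < n; ++i) {
    completed[i] = e.done[i];
    fin[i] = e.finish[i];
    completed_acts[i] = e.pos[i];
    if (!e.done[i]) {
      std::vector<int>& s = e.seqs[i];
      remaining[i] = IntegerVector(s.begin() + e.pos[i], s.end());
    } else {
      remaining[i] = IntegerVector(0);
    }
  }
  return List::create(
    _["completed"] = completed, _["finish_time"] = fin,
    _["activities_done"] = completed_acts, _["remaining"] = remaining,
    _["log"] = DataFrame::create(
      _["patient"] = wrap(e.log_pid), _["activity"] = wrap(e.log_act),
      _["start"] = wrap(e.log_start), _["end"] = wrap(e.log_end)
    )
  );
}
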