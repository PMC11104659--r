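group,category,term
location,home,home
location,home,house
location,home,bed
location,home,kitchen
location,home,living room
location,university/school,uni
location,university/school,college
location,university/school,school
location,university/school,campus
location,university/school,classroom
location,work,work
location,work,working
location,work,wfh
location,work,worked
location,work,job
location,work,office
location,work,coworkers
location,work,shift
location,restaurant/bar,restaurant
location,restaurant/bar,bar
location,restaurant/bar,cocktail
location,restaurant/bar,menu
location,restaurant/bar,server
location,restaurant/bar,waitress
location,party,party
location,party,festivity
location,party,gathering
location,party,wedding
location,party,reunion
location,workout,workout
location,workout,gym
location,workout,exercise
location,workout,routine
location,workout,crossfit
location,workout,cardio
location,workout,jog
location,workout,yoga
location,workout,fitness
location,supermarket,supermarket
location,supermarket,aisle
location,supermarket,grocery
location,supermarket,store
location,supermarket,checkout
location,supermarket,cashier
location,supermarket,cart
location,supermarket,walgreens
location,supermarket,711
location,supermarket,deli
location,supermarket,walmart
location,airport,airport
location,airport,layover
location,airport,flight
location,airport,plane
location,airport,airline
location,airport,delay
emotion,anxious/worried,anxious
emotion,anxious/worried,sad
emotion,anxious/worried,antsy
emotion,anxious/worried,panicky
emotion,anxious/worried,restless
emotion,anxious/worried,tense
emotion,sad,sad
emotion,sad,lonely
emotion,sad,depressed
emotion,sad,disappointed
emotion,sad,hopeless
emotion,sad,cry
emotion,stressed,stress
emotion,stressed,overwhelmed
emotion,stressed,overworked
emotion,stressed,unsettled
emotion,stressed,workload
emotion,tired,tired
emotion,tired,exhausted
emotion,tired,sick
emotion,tired,frazzled
emotion,tired,sluggish
emotion,tired,drained
emotion,tired,groggy
emotion,frustrated/angry,frustrated
emotion,frustrated/angry,irritated
emotion,frustrated/angry,snapping
emotion,frustrated/angry,pissy
emotion,frustrated/angry,mad
emotion,frustrated/angry,cranky
emotion,frustrated/angry,grumpy
emotion,frustrated/angry,ugh
emotion,happy,happy
emotion,happy,excited
emotion,happy,amazing
emotion,happy,awesome
emotion,happy,enjoying
emotion,happy,grateful
emotion,proud,proud
emotion,proud,accomplished
emotion,proud,milestone
emotion,proud,longest
emotion,bored,bored
emotion,bored,boredom
emotion,bored,boring
emotion,bored,unmotivated
emotion,bored,monotony
social,alone,alone
social,alone,isolated
social,alone,lonely
social,alone,cooped
social,alone,quarantining
social,friend(s),friend
social,friend(s),buddy
social,friend(s),pregaming
social,friend(s),groomsman
social,friend(s),friendsgiving
social,friend(s),bros
social,family,family
social,family,parent
social,family,dad
social,family,brother
social,family,mother
social,family,wife
social,family,sister
social,family,mom
social,partner,partner
social,partner,girlfriend
social,partner,husband
social,partner,boyfriend
social,partner,wife
social,partner,ex
social,partner,bf
social,colleague(s),colleague
social,colleague(s),coworkers
social,colleague(s),manager
social,colleague(s),networking
social,colleague(s),boss
social,colleague(s),meetups
social,colleague(s),supervisor
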